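#' Classify a suitability map into labelled classes
#'
#' Default classes follow the common cartographic convention:
#' `0.0-0.2` non-suitable, `0.2-0.4` low, `0.4-0.6` general, `0.6-0.8`
#' medium, `0.8-1.0` high. Intervals are left-closed right-open, the
#' last interval closed (so a value exactly on a break goes up).
#'
#' @param map a [suitability_map()] (or numeric vector of values in
#'   `[0,1]`).
#' @param breaks strictly increasing break vector.
#' @param labels class labels, one fewer than breaks.
#' @return factor of per-cell classes (`NA` at nodata).
#' @export
classify_suitability <- function(map,
                                 breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
                                 labels = c("non-suitable", "low",
                                            "general", "medium", "high")) {
  v <- if (inherits(map, "suitability_map")) map$values else map
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  if (length(labels) != length(breaks) - 1)
    stop("need one label per interval")
  # left-closed right-open, last interval closed
  idx <- findInterval(v, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx < 1 | idx > length(labels)] <- NA
  factor(labels[idx], levels = labels)
}

#' Signed suitability difference between two scenarios
#'
#' The direction convention follows the change analysis: for past
#' pairs `delta = current - past`, for future pairs
#' `delta = future - current`; in both cases positive values mean
#' expansion (suitability increasing along time) and negative values
#' contraction.
#'
#' @param reference the earlier map of the pair (past map, or the
#'   current map for future pairs).
#' @param comparison the later map (current map, or the future map).
#' @param direction `"past-to-current"` or `"current-to-future"`.
#' @return object of class `delta_map`: `grid`, `delta` (per-cell,
#'   `NA` where either input is nodata), `direction`, `scenario_pair`.
#' @export
suitability_delta <- function(reference, comparison,
                              direction = c("past-to-current",
                                            "current-to-future")) {
  direction <- match.arg(direction)
  if (!grids_identical(reference$grid, comparison$grid))
    stop("grid mismatch between the two suitability maps")
  if (!identical(reference$transform, comparison$transform))
    stop("suitability transforms differ")
  structure(list(grid = reference$grid,
                 delta = comparison$values - reference$values,
                 direction = direction,
                 scenario_pair = c(reference = reference$scenario,
                                   comparison = comparison$scenario)),
            class = "delta_map")
}

#' Threshold-free contraction/expansion accounting
#'
#' Bins every unmasked cell with current suitability at or above the
#' first break (default 0.03) by its current-suitability class, then
#' adds the cell's area to that class's contraction total `C` when its
#' suitability delta is negative and to the expansion total `E` when
#' positive (cells with exactly zero delta count to neither). No
#' minimum-change threshold is applied: the analysis is deliberately
#' threshold-free. Areas are reported in thousands of km2.
#'
#' @param current the current-scenario [suitability_map()].
#' @param delta a [suitability_delta()] map against the scenario of
#'   interest.
#' @param areas per-cell areas in km2 (see [cell_areas()]).
#' @param breaks current-suitability class breaks; cells below the
#'   first break are excluded.
#' @param min_delta optional minimum absolute delta for a cell to
#'   count (default 0, i.e. strict sign only).
#' @return a `change_table`: data.frame with one row per class
#'   (columns `class`, `C`, `E`, in 1e3 km2) and attributes
#'   `scenario`, `direction`, `total_C`, `total_E`, `net`.
#' @export
change_accounting <- function(current, delta, areas,
                              breaks = c(0.03, 0.1, 0.2, 0.4, 0.6, 1.0),
                              min_delta = 0) {
  if (!grids_identical(current$grid, delta$grid))
    stop("grid mismatch between current map and delta map")
  if (length(areas) != n_cells(current$grid))
    stop("areas must give one value per grid cell")
  s <- current$values; d <- delta$delta
  ok <- !is.na(s) & !is.na(d) & s >= breaks[1]
  cls <- findInterval(s[ok], breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  cls[cls > length(breaks) - 1] <- length(breaks) - 1
  a <- areas[ok]; dd <- d[ok]
  labs <- paste0(utils::head(breaks, -1), "-", breaks[-1])
  nclass <- length(breaks) - 1
  C <- E <- numeric(nclass)
  contr <- dd < -min_delta
  expa <- dd > min_delta
  for (k in seq_len(nclass)) {
    C[k] <- sum(a[contr & cls == k]) / 1e3
    E[k] <- sum(a[expa & cls == k]) / 1e3
  }
  tab <- data.frame(class = labs, C = C, E = E)
  change_table(tab, scenario = unname(delta$scenario_pair["comparison"]),
               direction = delta$direction,
               total_C = sum(C), total_E = sum(E))
}

#' Construct a change table
#'
#' @param per_class data.frame with columns `class`, `C`, `E` (areas in
#'   1e3 km2).
#' @param scenario scenario label.
#' @param direction delta direction.
#' @param total_C,total_E totals in 1e3 km2; default to the per-class
#'   sums, but may be supplied independently (e.g. from a published
#'   table whose totals are authoritative).
#' @return data.frame of class `change_table` with attributes
#'   `scenario`, `direction`, `total_C`, `total_E`, `net`.
#' @export
change_table <- function(per_class, scenario = NA_character_,
                         direction = NA_character_,
                         total_C = sum(per_class$C),
                         total_E = sum(per_class$E)) {
  stopifnot(all(c("class", "C", "E") %in% names(per_class)),
            all(per_class$C >= 0), all(per_class$E >= 0))
  structure(per_class,
            scenario = scenario, direction = direction,
            total_C = total_C, total_E = total_E,
            net = total_E - total_C,
            class = c("change_table", "data.frame"))
}

#' @export
print.change_table <- function(x, ...) {
  cat(sprintf("<change_table> scenario %s (%s)\n",
              attr(x, "scenario"), attr(x, "direction")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("  totals: C = %.4g, E = %.4g, net = %+.4g (1e3 km2)\n",
              attr(x, "total_C"), attr(x, "total_E"), attr(x, "net")))
  invisible(x)
}

#' Net suitability-area change of a scenario
#'
#' @param table a [change_table()].
#' @param unit `"1e3_km2"` (table units) or `"1e6_km2"` (millions of
#'   km2).
#' @return signed net change `total_E - total_C`.
#' @export
net_change <- function(table, unit = c("1e3_km2", "1e6_km2")) {
  unit <- match.arg(unit)
  net <- attr(table, "total_E") - attr(table, "total_C")
  if (unit == "1e6_km2") net / 1e3 else net
}

#' Area-weighted histogram of suitability changes
#'
#' Summarizes a delta map as a stacked histogram table: per delta bin
#' and per current-suitability class, the summed cell area. Bin edges
#' are symmetric over `[-1, 1]`. Because the bands partition the
#' current map, per-class band totals are identical across scenarios
#' that share the current map.
#'
#' @param delta a [suitability_delta()] map.
#' @param current_class per-cell factor of current classes (see
#'   [classify_suitability()]).
#' @param areas per-cell areas in km2.
#' @param n_bins number of delta bins (>= 2).
#' @return data.frame with columns `bin_lo`, `bin_hi`, one area column
#'   per class, and `total`.
#' @export
change_histogram <- function(delta, current_class, areas, n_bins = 40) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  edges <- seq(-1, 1, length.out = n_bins + 1)
  d <- delta$delta
  ok <- !is.na(d) & !is.na(current_class)
  bin <- findInterval(d[ok], edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  bin[bin < 1] <- 1; bin[bin > n_bins] <- n_bins
  cls <- droplevels(factor(current_class[ok]))
  a <- areas[ok]
  out <- data.frame(bin_lo = utils::head(edges, -1), bin_hi = edges[-1])
  for (lv in levels(cls)) {
    col <- numeric(n_bins)
    sel <- cls == lv
    agg <- tapply(a[sel], bin[sel], sum)
    col[as.integer(names(agg))] <- agg
    out[[lv]] <- col
  }
  out$total <- rowSums(out[, levels(cls), drop = FALSE])
  out
}

#' Per-variable distribution of scenario shifts
#'
#' For each layer shared by the two stacks, the per-cell difference
#' `scenario - current` is summarized by its 5/25/50/75/95% quantiles,
#' both over the whole (unmasked) study area and over the occurrence
#' cells.
#'
#' @param current,scenario two [env_stack()]s on the same grid.
#' @param occurrences an [occurrence_set()] with a `cell` column (see
#'   [dedup_to_grid()]); may be `NULL` to skip the occurrence rows.
#' @return data.frame with columns `variable`, `domain`
#'   (`"area"`/`"occurrences"`), `q05`, `q25`, `q50`, `q75`, `q95`.
#' @export
variable_shift_summary <- function(current, scenario, occurrences = NULL) {
  if (!grids_identical(current$grid, scenario$grid))
    stop("grid mismatch between stacks")
  shared <- intersect(names(current$layers), names(scenario$layers))
  if (length(shared) == 0) stop("no shared layers between stacks")
  mask <- current$nodata_mask | scenario$nodata_mask
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- list()
  for (v in shared) {
    diff <- scenario$layers[[v]] - current$layers[[v]]
    d_area <- diff[!mask]
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, domain = "area",
      t(stats::setNames(stats::quantile(d_area, qs, names = FALSE),
                        c("q05", "q25", "q50", "q75", "q95"))))
    if (!is.null(occurrences) && !is.null(occurrences$cell)) {
      d_occ <- diff[occurrences$cell]
      d_occ <- d_occ[!is.na(d_occ)]
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, domain = "occurrences",
        t(stats::setNames(stats::quantile(d_occ, qs, names = FALSE),
                          c("q05", "q25", "q50", "q75", "q95"))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- published change-area fixture -----------------------------------------

#' Published contraction/expansion areas for the strawberry tree
#'
#' Per-scenario, per-current-suitability-class contraction (C) and
#' expansion (E) areas (thousands of km2) from the published
#' suitability-change analysis of *Arbutus unedo* across two
#' palaeoclimate scenarios (LGM, MH) and four future scenarios
#' (RCP4.5/8.5 for 2050 and 2070), together with the published totals.
#' The published LGM expansion entries are internally inconsistent
#' (the per-class values do not sum to the published total); both are
#' stored as printed and [check_change_consistency()] reports the
#' discrepancy rather than guessing which entry is the typo.
#'
#' @return data.frame with columns `scenario`, `period`, `class`, `C`,
#'   `E`, `total_C`, `total_E` (totals repeated on each class row).
#' @export
published_change_areas <- function() {
  path <- system.file("extdata", "arbutus_change_areas.csv",
                      package = "maxsuit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Change tables from the published area fixture
#'
#' @param data output of [published_change_areas()] (default).
#' @return named list of [change_table()]s, one per scenario, with the
#'   published totals attached as authoritative.
#' @export
published_change_tables <- function(data = published_change_areas()) {
  out <- list()
  for (sc in unique(data$scenario)) {
    d <- data[data$scenario == sc, ]
    out[[sc]] <- change_table(
      data.frame(class = d$class, C = d$C, E = d$E),
      scenario = sc,
      direction = if (d$period[1] == "past") "past-to-current"
                  else "current-to-future",
      total_C = d$total_C[1], total_E = d$total_E[1])
  }
  out
}

#' Check per-class sums against stated totals
#'
#' @param table a [change_table()].
#' @param tol allowed absolute discrepancy in 1e3 km2 (0.5 covers
#'   rounding to whole units).
#' @return list with `C_consistent`, `E_consistent` (logicals) and the
#'   signed discrepancies `C_gap`, `E_gap` (stated minus summed).
#' @export
check_change_consistency <- function(table, tol = 0.5) {
  cg <- attr(table, "total_C") - sum(table$C)
  eg <- attr(table, "total_E") - sum(table$E)
  list(C_consistent = abs(cg) <= tol, E_consistent = abs(eg) <= tol,
       C_gap = cg, E_gap = eg)
}

#' Write a change table as CSV
#'
#' @param table a [change_table()].
#' @param path CSV output path.
#' @export
write_change_table <- function(table, path) {
  d <- as.data.frame(table)
  d$scenario <- attr(table, "scenario")
  tot <- data.frame(class = "total", C = attr(table, "total_C"),
                    E = attr(table, "total_E"),
                    scenario = attr(table, "scenario"))
  utils::write.csv(rbind(d, tot), path, row.names = FALSE)
  invisible(path)
}
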