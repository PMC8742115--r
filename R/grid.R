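#' Define an analysis grid
#'
#' A regular raster grid indexed row-major from the north-west corner.
#' Cells are half-open: a cell at row `i`, column `j` (0-based) covers
#' `[x0 + j*dx, x0 + (j+1)*dx)` in easting and `(y0 - (i+1)*dy, y0 - i*dy]`
#' in northing, so every point maps to exactly one cell.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param origin_x,origin_y coordinate of the north-west corner.
#' @param cell_size_x,cell_size_y positive cell sizes in grid units
#'   (degrees for geographic grids, metres otherwise).
#' @param crs_tag one of `"geographic-WGS84"`, `"equal-area-EPSG3035"`,
#'   `"synthetic-planar"`.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, origin_x, origin_y,
                      cell_size_x, cell_size_y,
                      crs_tag = "synthetic-planar") {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_x > 0, cell_size_y > 0)
  crs_tag <- match.arg(crs_tag,
    c("geographic-WGS84", "equal-area-EPSG3035", "synthetic-planar"))
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin_x = origin_x, origin_y = origin_y,
         cell_size_x = cell_size_x, cell_size_y = cell_size_y,
         crs_tag = crs_tag),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, NW origin (%g, %g), cell %g x %g, %s\n",
              x$n_rows, x$n_cols, x$origin_x, x$origin_y,
              x$cell_size_x, x$cell_size_y, x$crs_tag))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size_x - b$cell_size_x) < tol &&
    abs(a$cell_size_y - b$cell_size_y) < tol
}

#' Map points to grid cells
#'
#' Returns the 1-based row-major cell index of each point, or `NA` for
#' points outside the grid extent. Cell membership follows the half-open
#' convention of [grid_spec()].
#'
#' @param grid a [grid_spec()].
#' @param x,y point coordinates in grid units.
#' @return integer vector of cell indices (NA outside the grid).
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size_x)
  row <- floor((grid$origin_y - y) / grid$cell_size_y)
  idx <- row * grid$n_cols + col + 1L
  bad <- col < 0 | col >= grid$n_cols | row < 0 | row >= grid$n_rows
  idx[bad] <- NA_integer_
  as.integer(idx)
}

#' Coordinates of cell centers
#'
#' @param grid a [grid_spec()].
#' @param idx 1-based row-major cell indices (default: all cells).
#' @return data.frame with columns `x`, `y`.
#' @export
cell_centers <- function(grid, idx = seq_len(n_cells(grid))) {
  i0 <- idx - 1L
  row <- i0 %/% grid$n_cols
  col <- i0 %% grid$n_cols
  data.frame(
    x = grid$origin_x + (col + 0.5) * grid$cell_size_x,
    y = grid$origin_y - (row + 0.5) * grid$cell_size_y)
}

#' Bundle named environmental layers on a shared grid
#'
#' @param grid a [grid_spec()].
#' @param layers named list of numeric vectors, one value per cell in
#'   row-major order from the NW corner.
#' @param scenario scenario label (`"current"`, `"LGM"`, `"MH"`,
#'   `"RCP45-2050"`, ... or any `"synthetic-*"` tag).
#' @param nodata_mask logical vector, `TRUE` where the cell carries no
#'   data; masked cells are excluded from every downstream computation.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, scenario = "current",
                      nodata_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("layers must be uniquely named")
  nc <- n_cells(grid)
  for (l in nm) {
    if (length(layers[[l]]) != nc)
      stop(sprintf("layer '%s' has %d values; grid has %d cells",
                   l, length(layers[[l]]), nc))
  }
  if (is.null(nodata_mask)) nodata_mask <- rep(FALSE, nc)
  stopifnot(is.logical(nodata_mask), length(nodata_mask) == nc)
  # cells with NA in any layer are implicitly nodata
  for (l in nm) nodata_mask <- nodata_mask | is.na(layers[[l]])
  structure(list(grid = grid, layers = layers, scenario = scenario,
                 nodata_mask = nodata_mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> scenario '%s': %d layer(s) on %d x %d grid, %d masked cell(s)\n",
              x$scenario, length(x$layers), x$grid$n_rows, x$grid$n_cols,
              sum(x$nodata_mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell environmental values as a matrix
#'
#' @param stack an [env_stack()].
#' @param cells optional cell indices (default all cells).
#' @param vars optional layer subset.
#' @return numeric matrix, one row per cell, one column per layer.
#' @export
stack_values <- function(stack, cells = NULL, vars = names(stack$layers)) {
  if (is.null(cells)) cells <- seq_len(n_cells(stack$grid))
  m <- vapply(vars, function(v) {
    if (is.null(stack$layers[[v]])) stop(sprintf("layer '%s' not in stack", v))
    stack$layers[[v]][cells]
  }, numeric(length(cells)))
  m <- matrix(m, nrow = length(cells), dimnames = list(NULL, vars))
  m
}

# ---- ESRI ASCII grid IO -----------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Plain-text raster format: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' values row-major from the top row.
#'
#' @param path path to an `.asc` file.
#' @param crs_tag CRS tag passed to [grid_spec()].
#' @return list with `grid` (a [grid_spec()]), `values` (row-major
#'   vector, `NA` at nodata cells).
#' @export
read_ascii_grid <- function(path, crs_tag = "synthetic-planar") {
  if (!file.exists(path)) stop(sprintf("cannot read raster '%s'", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("'%s' is not an ESRI ASCII grid (missing header)", path))
  xll <- hdr$xllcorner %||% 0
  yll <- hdr$yllcorner %||% 0
  nodata <- hdr$nodata_value %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); ncl <- as.integer(hdr$ncols)
  if (length(vals) != nr * ncl)
    stop(sprintf("'%s': expected %d values, found %d", path, nr * ncl,
                 length(vals)))
  vals[vals == nodata] <- NA_real_
  grid <- grid_spec(nr, ncl,
                    origin_x = xll, origin_y = yll + nr * hdr$cellsize,
                    cell_size_x = hdr$cellsize, cell_size_y = hdr$cellsize,
                    crs_tag = crs_tag)
  list(grid = grid, values = vals)
}

#' Write an ESRI ASCII grid
#'
#' @param values row-major per-cell values (`NA` written as the nodata
#'   value).
#' @param grid a [grid_spec()] with equal x/y cell size.
#' @param path output path.
#' @param nodata nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  if (abs(grid$cell_size_x - grid$cell_size_y) > 1e-12)
    stop("ESRI ASCII grids require square cells")
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$origin_x),
    sprintf("yllcorner %.10g", grid$origin_y - grid$n_rows * grid$cell_size_y),
    sprintf("cellsize %.10g", grid$cell_size_x),
    sprintf("NODATA_value %g", nodata))
  rows <- vapply(seq_len(grid$n_rows), function(i) {
    paste(format(v[((i - 1) * grid$n_cols + 1):(i * grid$n_cols)],
                 trim = TRUE, digits = 15), collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a stack of raster layers sharing one grid
#'
#' @param paths named character vector of ESRI ASCII grid paths; names
#'   become layer names (defaults to file basenames without extension).
#' @param scenario scenario label for the stack.
#' @param crs_tag CRS tag of the grids.
#' @return an [env_stack()]; the nodata mask is the union of each
#'   file's nodata cells.
#' @export
read_env_stack <- function(paths, scenario = "current",
                           crs_tag = "synthetic-planar") {
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  first <- read_ascii_grid(paths[[1]], crs_tag)
  layers <- list()
  layers[[names(paths)[1]]] <- first$values
  if (length(paths) > 1) {
    for (k in 2:length(paths)) {
      g <- read_ascii_grid(paths[[k]], crs_tag)
      if (!grids_identical(g$grid, first$grid))
        stop(sprintf("grid mismatch: layer '%s' does not match '%s'",
                     names(paths)[k], names(paths)[1]))
      layers[[names(paths)[k]]] <- g$values
    }
  }
  env_stack(first$grid, layers, scenario = scenario)
}

# ---- occurrences ------------------------------------------------------------

#' Read species occurrences from CSV
#'
#' Expects header columns `longitude,latitude` and optionally `source`,
#' decimal degrees WGS84.
#'
#' @param path CSV path.
#' @return data.frame of class `occurrence_set` with columns
#'   `longitude`, `latitude`, `source`.
#' @export
read_occurrences <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("longitude", "latitude") %in% names(d)))
    stop("occurrence CSV needs 'longitude' and 'latitude' columns")
  if (is.null(d$source)) d$source <- NA_character_
  occurrence_set(d$longitude, d$latitude, d$source)
}

#' Construct an occurrence set
#'
#' @param longitude,latitude decimal degrees WGS84.
#' @param source optional free-text provenance per record.
#' @return data.frame of class `occurrence_set`.
#' @export
occurrence_set <- function(longitude, latitude, source = NA_character_) {
  stopifnot(length(longitude) == length(latitude))
  if (any(longitude < -180 | longitude > 180, na.rm = TRUE) ||
      any(latitude < -90 | latitude > 90, na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  d <- data.frame(longitude = longitude, latitude = latitude,
                  source = rep_len(source, length(longitude)),
                  stringsAsFactors = FALSE)
  class(d) <- c("occurrence_set", "data.frame")
  d
}

#' Reduce occurrences to one record per grid cell
#'
#' Spatial thinning against autocorrelation: each occupied cell keeps
#' its first record in input order. Records outside the grid extent, or
#' falling on masked cells when a mask is supplied, are dropped; the
#' dropped count is reported as a message. Idempotent.
#'
#' @param occ an [occurrence_set()].
#' @param grid a [grid_spec()].
#' @param nodata_mask optional per-cell logical mask; records on masked
#'   cells are dropped.
#' @return the thinned `occurrence_set`, with a `cell` column giving
#'   the retained record's grid cell index.
#' @export
dedup_to_grid <- function(occ, grid, nodata_mask = NULL) {
  if (nrow(occ) == 0) {
    occ$cell <- integer(0)
    return(occ)
  }
  idx <- cell_index(grid, occ$longitude, occ$latitude)
  keep <- !is.na(idx)
  if (!is.null(nodata_mask)) keep[keep] <- !nodata_mask[idx[keep]]
  dropped_outside <- sum(!keep)
  d <- occ[keep, , drop = FALSE]
  idx <- idx[keep]
  first <- !duplicated(idx)
  out <- d[first, , drop = FALSE]
  out$cell <- idx[first]
  rownames(out) <- NULL
  if (dropped_outside > 0)
    message(sprintf("dedup_to_grid: dropped %d record(s) outside the grid or on masked cells",
                    dropped_outside))
  message(sprintf("dedup_to_grid: %d record(s) -> %d cell(s)", nrow(occ),
                  nrow(out)))
  class(out) <- c("occurrence_set", "data.frame")
  out
}

# ---- derived layers ---------------------------------------------------------

#' Terrain slope from an elevation layer
#'
#' Horn's 3x3 finite-difference kernel with edge replication at the
#' borders; the result is in degrees in `[0, 90]`.
#'
#' @param elevation per-cell elevation, row-major (same units as the
#'   cell sizes unless `z_factor` rescales them).
#' @param grid a [grid_spec()].
#' @param z_factor multiplier converting elevation units into grid
#'   units (e.g. 1 for metres on a metric grid).
#' @return per-cell slope in degrees, row-major.
#' @export
compute_slope <- function(elevation, grid, z_factor = 1) {
  nr <- grid$n_rows; ncl <- grid$n_cols
  if (nr < 2 || ncl < 2) stop("grid too small for slope")
  z <- matrix(elevation, nrow = nr, ncol = ncl, byrow = TRUE) * z_factor
  # edge replication
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, ncl, drop = FALSE])
  ri <- 2:(nr + 1); ci <- 2:(ncl + 1)
  a <- zp[ri - 1, ci - 1]; b <- zp[ri - 1, ci]; cc <- zp[ri - 1, ci + 1]
  d <- zp[ri,     ci - 1];                      f <- zp[ri,     ci + 1]
  g <- zp[ri + 1, ci - 1]; h <- zp[ri + 1, ci]; i2 <- zp[ri + 1, ci + 1]
  dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + g)) / (8 * grid$cell_size_x)
  dzdy <- ((g + 2 * h + i2) - (a + 2 * b + cc)) / (8 * grid$cell_size_y)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  as.vector(t(slope))
}

#' Per-cell areas in square kilometres
#'
#' Equal-area and planar grids have constant cell area
#' `cell_size_x * cell_size_y` (cell sizes in metres). Geographic grids
#' use the spherical approximation
#' `R^2 * dlon * dlat * cos(lat_center)` with `R = 6371` km and cell
#' sizes in degrees.
#'
#' @param grid a [grid_spec()].
#' @return per-cell area in km2, row-major.
#' @export
cell_areas <- function(grid) {
  nc <- n_cells(grid)
  if (grid$crs_tag %in% c("equal-area-EPSG3035", "synthetic-planar")) {
    rep(grid$cell_size_x * grid$cell_size_y / 1e6, nc)
  } else if (grid$crs_tag == "geographic-WGS84") {
    R <- 6371
    dlam <- grid$cell_size_x * pi / 180
    dphi <- grid$cell_size_y * pi / 180
    rowlat <- grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size_y
    per_row <- R^2 * dlam * dphi * cos(rowlat * pi / 180)
    rep(per_row, each = grid$n_cols)
  } else {
    stop(sprintf("unknown crs_tag '%s'", grid$crs_tag))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
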