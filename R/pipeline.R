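#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] expects, filled
#' with the synthetic benchmark so the whole pipeline runs without any
#' external data. For a real study, set `synthetic = FALSE` and supply
#' `occurrences` (CSV path) and `stacks` (named list: scenario label
#' -> named vector of ESRI ASCII grid paths, one of them named
#' `current`).
#'
#' @param out_dir output directory for the run.
#' @param seed base seed for every stochastic stage.
#' @return configuration list.
#' @export
default_config <- function(out_dir = tempfile("maxsuit_run_"), seed = 42) {
  list(
    synthetic = TRUE,
    seed = seed,
    out_dir = out_dir,
    occurrences = NULL, stacks = NULL, crs_tag = "geographic-WGS84",
    n_background = 2000,
    classes = c("linear", "quadratic", "hinge"),
    n_hinge_knots = 8,
    reg_multiplier = 1, max_iter = 2500, tol = 1e-5,
    k_first_stage = 5, auc_floor = 0.995,
    class_breaks = c(0.03, 0.1, 0.2, 0.4, 0.6, 1.0),
    suit_breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1.0),
    n_bins = 40)
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package needed to read YAML configs")
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  utils::modifyList(default_config(), config)
}

#' Run the full suitability-modelling pipeline
#'
#' Orchestrates every stage deterministically: occurrence
#' deduplication, background sampling, first-stage RM variable
#' selection, full model fit, variable diagnostics, backward
#' elimination under the AUC floor, projection onto every scenario
#' stack, and per-scenario change accounting, delta histograms and
#' variable-shift summaries. All tables are written as CSV, suitability
#' maps as ESRI ASCII grids, the model and a re-run manifest as JSON.
#'
#' @param config a configuration list (see [default_config()]) or a
#'   path to a YAML/JSON file with the same fields.
#' @return (invisibly) list with the fitted models, selections, maps
#'   and change tables; side effect: the populated `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[maxsuit] ", sprintf(...))

  # -- inputs -----------------------------------------------------------
  if (isTRUE(cfg$synthetic)) {
    log_msg("generating synthetic study (seed %d)", cfg$seed)
    bench <- synthetic_benchmark(cfg$seed)
    current <- bench$stack
    occ <- bench$occurrences[, c("longitude", "latitude", "source")]
    class(occ) <- c("occurrence_set", "data.frame")
    scen_stacks <- lapply(names(default_scenario_shifts()), function(sc)
      apply_scenario_shift(current, default_scenario_shifts()[[sc]], sc))
    names(scen_stacks) <- names(default_scenario_shifts())
  } else {
    if (is.null(cfg$stacks) || is.null(cfg$stacks$current))
      stop("config is missing the 'current' scenario stack")
    log_msg("reading stacks and occurrences")
    current <- read_env_stack(cfg$stacks$current, scenario = "current",
                              crs_tag = cfg$crs_tag)
    others <- setdiff(names(cfg$stacks), "current")
    scen_stacks <- lapply(others, function(sc) {
      missing <- cfg$stacks[[sc]][!file.exists(cfg$stacks[[sc]])]
      if (length(missing) > 0)
        stop(sprintf("scenario '%s': missing raster file(s) %s", sc,
                     paste(missing, collapse = ", ")))
      read_env_stack(cfg$stacks[[sc]], scenario = sc,
                     crs_tag = cfg$crs_tag)
    })
    names(scen_stacks) <- others
    occ <- read_occurrences(cfg$occurrences)
  }

  # -- dedup ------------------------------------------------------------
  occ <- dedup_to_grid(occ, current$grid, current$nodata_mask)
  log_msg("%d occurrence cell(s) after deduplication", nrow(occ))

  # -- first-stage variable selection -----------------------------------
  corr <- background_correlation(current, n_sample = cfg$n_background,
                                 seed = cfg$seed)
  k <- min(cfg$k_first_stage, length(corr$variables) - 1)
  sel1 <- select_subset(corr, k = k)
  log_msg("first-stage subset (k=%d, RM=%.4f): %s", k, sel1$rm_value,
          paste(sel1$subset, collapse = ", "))
  write_subset_report(sel1, file.path(cfg$out_dir, "subset_rm.csv"))

  # -- full fit ---------------------------------------------------------
  bg_cells <- sample_background(current, cfg$n_background,
                                seed = cfg$seed + 2)
  pres <- stack_values(current, occ$cell, sel1$subset)
  bg <- stack_values(current, bg_cells, sel1$subset)
  fit_full <- maxent(pres, bg, classes = cfg$classes,
                     n_hinge_knots = cfg$n_hinge_knots,
                     reg_multiplier = cfg$reg_multiplier,
                     max_iter = cfg$max_iter, tol = cfg$tol)
  log_msg("full model: gain %.4f, AUC %.4f", fit_full$training$gain,
          fit_full$training$train_auc)
  write_maxent_json(fit_full, file.path(cfg$out_dir, "model_full.json"))

  # -- diagnostics + second-stage reduction -----------------------------
  metrics <- variable_metrics(fit_full, seed = cfg$seed + 3)
  red <- rank_and_reduce(fit_full, metrics, auc_floor = cfg$auc_floor)
  log_msg("selected %d variable(s): %s", length(red$selected),
          paste(red$selected, collapse = ", "))
  write_metrics_report(metrics, file.path(cfg$out_dir, "variable_metrics.csv"),
                       selected = red$selected)
  model <- red$model
  write_maxent_json(model, file.path(cfg$out_dir, "model_selected.json"))

  # -- projection and change analysis -----------------------------------
  areas <- cell_areas(current$grid)
  suit_cur <- predict(model, current)
  write_ascii_grid(suit_cur$values, current$grid,
                   file.path(cfg$out_dir, "suitability_current.asc"))
  cls_cur <- classify_suitability(suit_cur, cfg$suit_breaks)
  change_tables <- list()
  for (sc in names(scen_stacks)) {
    st <- scen_stacks[[sc]]
    suit_sc <- predict(model, st)
    write_ascii_grid(suit_sc$values, st$grid,
                     file.path(cfg$out_dir, sprintf("suitability_%s.asc", sc)))
    past <- grepl("LGM|MH", sc)
    dl <- if (past) suitability_delta(suit_sc, suit_cur, "past-to-current")
          else suitability_delta(suit_cur, suit_sc, "current-to-future")
    ct <- change_accounting(suit_cur, dl, areas, breaks = cfg$class_breaks)
    attr(ct, "scenario") <- sc
    change_tables[[sc]] <- ct
    write_change_table(ct, file.path(cfg$out_dir,
                                     sprintf("change_%s.csv", sc)))
    hist <- change_histogram(dl, cls_cur, areas, n_bins = cfg$n_bins)
    utils::write.csv(hist, file.path(cfg$out_dir,
                                     sprintf("delta_hist_%s.csv", sc)),
                     row.names = FALSE)
    shifts <- variable_shift_summary(current, st, occ)
    utils::write.csv(shifts, file.path(cfg$out_dir,
                                       sprintf("shifts_%s.csv", sc)),
                     row.names = FALSE)
    log_msg("scenario %s: net change %+.1f (1e3 km2)", sc, net_change(ct))
  }

  # -- manifest ---------------------------------------------------------
  manifest <- list(
    config = cfg[setdiff(names(cfg), "stacks")],
    package_version = as.character(utils::packageVersion("maxsuit")),
    n_occurrences = nrow(occ),
    first_stage_subset = sel1$subset,
    selected_variables = red$selected,
    full_gain = fit_full$training$gain,
    full_auc = fit_full$training$train_auc,
    selected_auc = model$training$train_auc,
    scenarios = names(scen_stacks),
    net_change_1e3_km2 = lapply(change_tables, net_change))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, occurrences = occ, subset = sel1,
                 model_full = fit_full, metrics = metrics,
                 reduction = red, model = model,
                 suitability_current = suit_cur,
                 change_tables = change_tables,
                 out_dir = cfg$out_dir))
}
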