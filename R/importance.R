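#' Percent contribution of each variable to the training gain
#'
#' Credits every positive gain increment along the fitting path to the
#' updated feature's source variable(s) (split equally for product
#' features) and normalizes to percentages. The statistic is
#' path-dependent by construction: it describes the fit trajectory,
#' not the model alone.
#'
#' @param model a fitted [maxent()] model (its `trace` must be
#'   present).
#' @return named numeric vector of percentages summing to 100 (all
#'   zeros if the fit never improved).
#' @export
percent_contribution <- function(model) {
  if (is.null(model$trace)) stop("model carries no fit trace")
  vars <- model$variables
  contrib <- stats::setNames(numeric(length(vars)), vars)
  tab <- model$features$table
  tr <- model$trace
  for (r in seq_len(nrow(tr))) {
    f <- tr$feature[r]
    d <- tr$gain_delta[r]
    if (d <= 0) next
    v1 <- tab$var1[f]; v2 <- tab$var2[f]
    if (!is.na(v2)) {
      contrib[v1] <- contrib[v1] + d / 2
      contrib[v2] <- contrib[v2] + d / 2
    } else {
      contrib[v1] <- contrib[v1] + d
    }
  }
  tot <- sum(contrib)
  if (tot <= 0) return(contrib)
  100 * contrib / tot
}

#' Permutation importance of each variable
#'
#' For each variable, its values are permuted jointly across the
#' presence and background rows (one shared permutation), the fixed
#' model is re-evaluated, and the drop in training AUC (floored at 0)
#' is recorded. Drops are normalized to percentages.
#'
#' @param model a fitted [maxent()] model.
#' @param seed integer seed for the permutations.
#' @param reps permutations per variable (drops are averaged).
#' @return named numeric vector of percentages summing to 100.
#' @export
permutation_importance <- function(model, seed = 1, reps = 1) {
  pres <- model$presence; bg <- model$background
  X <- rbind(pres, bg)
  m <- nrow(pres)
  base_scores <- predict(model, X, type = "raw")
  base_auc <- auc(base_scores[seq_len(m)], base_scores[-seq_len(m)])
  set.seed(seed)
  drops <- stats::setNames(numeric(length(model$variables)),
                           model$variables)
  used <- unique(c(model$features$table$var1,
                   stats::na.omit(model$features$table$var2)))
  for (v in model$variables) {
    if (!(v %in% used)) next  # variable absent from all features
    acc <- 0
    for (r in seq_len(reps)) {
      Xp <- X
      Xp[, v] <- X[sample(nrow(X)), v]
      sc <- suppressWarnings(predict(model, Xp, type = "raw"))
      a <- suppressWarnings(auc(sc[seq_len(m)], sc[-seq_len(m)]))
      acc <- acc + max(base_auc - a, 0)
    }
    drops[v] <- acc / reps
  }
  tot <- sum(drops)
  if (tot <= 0) {
    warning("no permutation reduced the AUC; importances undefined (all 0)")
    return(drops)
  }
  100 * drops / tot
}

#' Jackknife gain ratios per variable
#'
#' Refits the model `2p` times: once without each variable
#' (`without`) and once with each variable alone (`with_only`). Each
#' submodel's training gain is reported as a ratio to the full model's
#' gain.
#'
#' @param model a fitted [maxent()] model (data and settings are taken
#'   from it).
#' @return data.frame with columns `variable`, `without_ratio`,
#'   `only_ratio`.
#' @export
jackknife <- function(model) {
  vars <- model$variables
  if (length(vars) < 2) stop("jackknife needs at least 2 variables")
  g_full <- model$training$gain
  if (g_full <= 0) stop("full-model gain is not positive; ratios undefined")
  refit_gain <- function(keep) {
    fit <- refit_on(model, keep)
    fit$training$gain
  }
  without <- vapply(vars, function(v) refit_gain(setdiff(vars, v)),
                    numeric(1))
  only <- vapply(vars, function(v) refit_gain(v), numeric(1))
  data.frame(variable = vars, without_ratio = without / g_full,
             only_ratio = only / g_full, row.names = NULL)
}

# Refit the model on a subset of its variables, same data and settings.
refit_on <- function(model, vars) {
  maxent(model$presence[, vars, drop = FALSE],
         model$background[, vars, drop = FALSE],
         classes = model$settings$classes,
         n_hinge_knots = model$settings$n_hinge_knots,
         reg_multiplier = model$reg_multiplier,
         max_iter = model$training$max_iter, tol = model$training$tol,
         class_beta = model$settings$class_beta)
}

#' Variable metrics table with per-metric and aggregate ranks
#'
#' Combines percent contribution, permutation importance and the two
#' jackknife gain ratios into one table. Rank directions: higher
#' percent contribution, higher permutation importance, LOWER
#' without-gain ratio (the model loses more without the variable) and
#' higher with-only ratio all mean more important (rank 1 = most
#' important; ties share the mean rank). The aggregate rank is the
#' unweighted mean of the four.
#'
#' @param model a fitted [maxent()] model.
#' @param seed seed for the permutation importance.
#' @param perm_reps permutations per variable.
#' @return data.frame of class `variable_metrics`, one row per
#'   variable, ordered by aggregate rank.
#' @export
variable_metrics <- function(model, seed = 1, perm_reps = 1) {
  pc <- percent_contribution(model)
  pi_ <- permutation_importance(model, seed = seed, reps = perm_reps)
  jk <- jackknife(model)
  d <- data.frame(
    variable = model$variables,
    percent_contribution = as.numeric(pc[model$variables]),
    permutation_importance = as.numeric(pi_[model$variables]),
    jk_without_gain_ratio = jk$without_ratio[match(model$variables,
                                                   jk$variable)],
    jk_only_gain_ratio = jk$only_ratio[match(model$variables, jk$variable)],
    row.names = NULL)
  d$rank_contribution <- rank(-d$percent_contribution)
  d$rank_permutation <- rank(-d$permutation_importance)
  d$rank_jk_without <- rank(d$jk_without_gain_ratio)
  d$rank_jk_only <- rank(-d$jk_only_gain_ratio)
  d$aggregate_rank <- (d$rank_contribution + d$rank_permutation +
                         d$rank_jk_without + d$rank_jk_only) / 4
  # stable order: aggregate rank, then permutation importance, then name
  d <- d[order(d$aggregate_rank, -d$permutation_importance, d$variable), ]
  rownames(d) <- NULL
  class(d) <- c("variable_metrics", "data.frame")
  d
}

#' Backward elimination under a training-AUC floor
#'
#' Second-stage variable selection: starting from the full model,
#' iteratively drops the variable with the worst aggregate rank
#' (ranking frozen from the full model, not recomputed between drops),
#' refits, and keeps dropping while the refit training AUC stays at or
#' above `auc_floor` times the full model's AUC. Returns the smallest
#' passing set.
#'
#' @param model the full fitted [maxent()] model.
#' @param metrics a [variable_metrics()] table (computed from `model`
#'   if omitted).
#' @param auc_floor fraction of the full-model AUC that must be
#'   retained (study default 0.995).
#' @param seed seed forwarded to [variable_metrics()] when computed
#'   here.
#' @return list of class `reduction_result`: `selected` (variable
#'   names), `model` (refit on the selected set), `full_auc`, `audit`
#'   (one row per elimination step: variable dropped, refit AUC, AUC
#'   ratio, accepted).
#' @export
rank_and_reduce <- function(model, metrics = NULL, auc_floor = 0.995,
                            seed = 1) {
  if (is.null(metrics)) metrics <- variable_metrics(model, seed = seed)
  full_auc <- model$training$train_auc
  drop_order <- rev(metrics$variable)  # worst aggregate rank first
  current <- sort(metrics$variable)
  current_model <- model
  audit <- list()
  if (auc_floor > 1) {
    warning("auc_floor above 1 is unreachable; returning the full set")
    return(structure(list(selected = current, model = model,
                          full_auc = full_auc,
                          audit = data.frame()),
                     class = "reduction_result"))
  }
  for (v in drop_order) {
    if (length(current) <= 1) break
    cand <- setdiff(current, v)
    fit <- refit_on(model, cand)
    ratio <- fit$training$train_auc / full_auc
    ok <- fit$training$train_auc >= auc_floor * full_auc
    audit[[length(audit) + 1]] <- data.frame(
      dropped = v, n_vars = length(cand), auc = fit$training$train_auc,
      auc_ratio = ratio, accepted = ok)
    if (!ok) break
    current <- cand
    current_model <- fit
  }
  structure(list(selected = current, model = current_model,
                 full_auc = full_auc,
                 audit = do.call(rbind, audit) %||% data.frame()),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat(sprintf("<reduction_result> %d variable(s) kept (full AUC %.4f)\n",
              length(x$selected), x$full_auc))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$audit) > 0) {
    cat("  elimination steps:\n")
    print(x$audit, row.names = FALSE)
  }
  invisible(x)
}

#' Marginal response curve of one variable
#'
#' Evaluates cloglog suitability over `n_points` spanning the
#' variable's training range while holding every other variable at its
#' background mean.
#'
#' @param model a fitted [maxent()] model.
#' @param variable variable name.
#' @param n_points curve resolution.
#' @return data.frame with columns `x` (variable value) and
#'   `suitability`.
#' @export
response_curve <- function(model, variable, n_points = 101) {
  used <- unique(c(model$features$table$var1,
                   stats::na.omit(model$features$table$var2)))
  if (!(variable %in% used))
    stop(sprintf("variable '%s' is not used by the model", variable))
  lo <- model$features$normalization$lo
  hi <- model$features$normalization$hi
  xs <- seq(lo[variable], hi[variable], length.out = n_points)
  means <- colMeans(model$background)
  nd <- matrix(rep(means, each = n_points), nrow = n_points,
               dimnames = list(NULL, names(means)))
  nd[, variable] <- xs
  data.frame(x = xs, suitability = predict(model, nd, type = "cloglog"))
}

#' Plot response curves of a fitted model
#'
#' @param x a fitted [maxent()] model.
#' @param vars variables to plot (default: all used by the model).
#' @param n_points curve resolution.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.maxent <- function(x, vars = NULL, n_points = 101, ...) {
  used <- unique(c(x$features$table$var1,
                   stats::na.omit(x$features$table$var2)))
  if (is.null(vars)) vars <- used
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(vars)))
  on.exit(graphics::par(old))
  for (v in vars) {
    rc <- response_curve(x, v, n_points)
    graphics::plot(rc$x, rc$suitability, type = "l", xlab = v,
                   ylab = "suitability", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Write a variable-metrics report
#'
#' One row per variable: contribution, importance, jackknife ratios,
#' ranks, aggregate rank and whether the backward elimination kept it.
#'
#' @param metrics a [variable_metrics()] table.
#' @param path CSV output path.
#' @param selected optional character vector of kept variables (adds a
#'   `kept` column).
#' @export
write_metrics_report <- function(metrics, path, selected = NULL) {
  d <- as.data.frame(metrics)
  if (!is.null(selected)) d$kept <- d$variable %in% selected
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
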