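#' Sample background cells from an environmental stack
#'
#' Uniform sample without replacement from the unmasked cells,
#' reproducible under `seed`. Background cells represent the available
#' environment against which presences are contrasted.
#'
#' @param stack an [env_stack()].
#' @param n number of cells to draw (capped at the number of unmasked
#'   cells with a warning).
#' @param seed integer seed.
#' @return integer vector of cell indices.
#' @export
sample_background <- function(stack, n = 1e5, seed = 1) {
  cells <- which(!stack$nodata_mask)
  if (length(cells) == 0) stop("stack is fully masked")
  if (n < 1) stop("n must be >= 1")
  if (n > length(cells)) {
    warning("n exceeds unmasked cells; using all of them")
    n <- length(cells)
  }
  set.seed(seed)
  sort(sample(cells, n))
}

# ---- feature expansion ------------------------------------------------------

# Scale a raw variable to [0,1] on its training range, clamping outside.
scale01 <- function(v, lo, hi) {
  v <- pmin(pmax(v, lo), hi)
  if (hi > lo) (v - lo) / (hi - lo) else rep(0, length(v))
}

#' Expand environmental variables into model features
#'
#' Builds the feature matrix of a maximum-entropy model from raw
#' variable values. Variables are min-max scaled to `[0,1]` on the
#' training data; when projecting, values are clamped to the training
#' range first. Feature classes: `linear` (scaled value), `quadratic`
#' (scaled value squared), `product` (pairwise products of scaled
#' values), `hinge` (forward `max(0, v-k)/(max-k)` and reverse
#' `max(0, k-v)/(k-min)` ramps at quantile-spaced knots) and
#' `threshold` (indicator `v > k`).
#'
#' @param X matrix or data.frame of raw values, one row per cell.
#' @param classes feature classes to enable.
#' @param n_hinge_knots knots per variable per orientation for hinge
#'   and threshold features, placed at equal quantiles of the training
#'   values.
#' @param spec optional feature specification from a previous call
#'   (training); when given, features are re-evaluated with clamping
#'   instead of re-derived.
#' @return list of class `feature_set`: `F` (feature matrix), `spec`
#'   (per-feature class/variables/knot/orientation), `normalization`
#'   (per-variable training min/max), `classes`, `n_hinge_knots`.
#' @export
build_features <- function(X,
                           classes = c("linear", "quadratic", "hinge"),
                           n_hinge_knots = 8, spec = NULL) {
  X <- as.matrix(X)
  if (!is.null(spec)) return(eval_features(X, spec))
  classes <- match.arg(classes,
    c("linear", "quadratic", "product", "hinge", "threshold"),
    several.ok = TRUE)
  vars <- colnames(X)
  if (is.null(vars)) stop("X must have column names")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  dead <- vars[hi <= lo]
  if (length(dead) > 0) {
    warning(sprintf("zero-variance variable(s) skipped: %s",
                    paste(dead, collapse = ", ")))
    vars <- setdiff(vars, dead)
    if (length(vars) == 0) stop("no usable variables")
  }
  rows <- list()
  add <- function(class, var1, var2 = NA, knot = NA, orientation = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      class = class, var1 = var1, var2 = var2, knot = knot,
      orientation = orientation, stringsAsFactors = FALSE)
  }
  for (v in vars) {
    if ("linear" %in% classes) add("linear", v)
    if ("quadratic" %in% classes) add("quadratic", v)
  }
  if ("product" %in% classes && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1))
      for (j in (i + 1):length(vars))
        add("product", vars[i], vars[j])
  }
  if (any(c("hinge", "threshold") %in% classes)) {
    probs <- seq_len(n_hinge_knots) / (n_hinge_knots + 1)
    for (v in vars) {
      s <- scale01(X[, v], lo[v], hi[v])
      knots <- unique(stats::quantile(s, probs, names = FALSE, type = 7))
      if ("hinge" %in% classes) {
        for (k in knots[knots < 1]) add("hinge", v, knot = k,
                                        orientation = "forward")
        for (k in knots[knots > 0]) add("hinge", v, knot = k,
                                        orientation = "reverse")
      }
      if ("threshold" %in% classes)
        for (k in knots[knots > 0 & knots < 1]) add("threshold", v, knot = k)
    }
  }
  spec <- list(table = do.call(rbind, rows),
               normalization = list(lo = lo[vars], hi = hi[vars]),
               classes = classes, n_hinge_knots = n_hinge_knots)
  class(spec) <- "feature_spec"
  eval_features(X, spec)
}

# Evaluate a frozen feature specification on (possibly new) raw data,
# clamping each variable to its training range.
eval_features <- function(X, spec) {
  if (inherits(spec, "feature_set")) spec <- spec$spec
  tab <- spec$table
  lo <- spec$normalization$lo; hi <- spec$normalization$hi
  vars <- names(lo)
  miss <- setdiff(unique(c(tab$var1, stats::na.omit(tab$var2))), colnames(X))
  if (length(miss) > 0)
    stop(sprintf("missing layer(s): %s", paste(miss, collapse = ", ")))
  S <- vapply(vars, function(v) scale01(X[, v], lo[v], hi[v]),
              numeric(nrow(X)))
  S <- matrix(S, nrow = nrow(X), dimnames = list(NULL, vars))
  if (any(!is.finite(S))) {
    bad <- vars[colSums(!is.finite(S)) > 0]
    stop(sprintf("non-finite values in feature input(s): %s",
                 paste(bad, collapse = ", ")))
  }
  F <- matrix(0, nrow(X), nrow(tab))
  nm <- character(nrow(tab))
  for (r in seq_len(nrow(tab))) {
    v <- S[, tab$var1[r]]
    F[, r] <- switch(tab$class[r],
      linear = v,
      quadratic = v^2,
      product = v * S[, tab$var2[r]],
      hinge = if (tab$orientation[r] == "forward")
          pmax(0, v - tab$knot[r]) / (1 - tab$knot[r])
        else pmax(0, tab$knot[r] - v) / tab$knot[r],
      threshold = as.numeric(v > tab$knot[r]))
    nm[r] <- switch(tab$class[r],
      linear = tab$var1[r],
      quadratic = paste0(tab$var1[r], "^2"),
      product = paste0(tab$var1[r], ":", tab$var2[r]),
      hinge = sprintf("h(%s%s%.3f)", tab$var1[r],
                      if (tab$orientation[r] == "forward") ">" else "<",
                      tab$knot[r]),
      threshold = sprintf("t(%s>%.3f)", tab$var1[r], tab$knot[r]))
  }
  colnames(F) <- nm
  structure(list(F = F, spec = spec,
                 normalization = spec$normalization,
                 classes = spec$classes,
                 n_hinge_knots = spec$n_hinge_knots),
            class = "feature_set")
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# ---- the fitter -------------------------------------------------------------

#' Fit a presence-only maximum-entropy suitability model
#'
#' Estimates the distribution of a species over a landscape sample
#' (presences plus background cells) that is as close to uniform as the
#' presence data allow. The fitter maximizes the L1-regularized gain
#'
#' `G(lambda) = mean_presence(lambda . f) - log mean_landscape exp(lambda . f)
#'              - sum_j beta_j |lambda_j|`
#'
#' a concave objective, by cyclic coordinate-wise proximal Newton
#' ascent with exact backtracking, so the gain never decreases across
#' iterations. Per-feature penalties are
#' `beta_j = reg_multiplier * c_class * s_j / sqrt(m)` with `s_j` the
#' feature's presence-sample standard deviation and `m` the presence
#' count. The landscape sample is the union of presence and background
#' cells; exact duplicate cells are dropped defensively.
#'
#' @param presence matrix/data.frame of environmental values at
#'   presence cells (one row per cell, named columns).
#' @param background same layout for background cells.
#' @param classes feature classes to enable (see [build_features()]).
#' @param n_hinge_knots hinge/threshold knots per variable per
#'   orientation.
#' @param reg_multiplier global regularization multiplier (the study
#'   default is 1; 0 removes the penalty entirely).
#' @param max_iter maximum number of coordinate-descent cycles.
#' @param tol relative gain-change convergence tolerance per cycle.
#' @param class_beta per-class base regularization constants.
#' @return an object of class `maxent` with components `lambda`,
#'   `beta`, `features` (frozen feature spec), `logZ`, `H` (entropy of
#'   the fitted distribution), `training` (gain, train_auc, counts,
#'   convergence), `trace` (per-update feature and gain delta),
#'   `gain_path` (per-cycle gain), and the training `presence` /
#'   `background` matrices.
#' @seealso [predict.maxent()], [response_curve()], [auc()]
#' @export
maxent <- function(presence, background,
                   classes = c("linear", "quadratic", "hinge"),
                   n_hinge_knots = 8, reg_multiplier = 1,
                   max_iter = 2500, tol = 1e-5,
                   class_beta = c(linear = 1, quadratic = 1, product = 1,
                                  hinge = 0.5, threshold = 1)) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  if (nrow(presence) < 1) stop("no presence records")
  if (!identical(colnames(presence), colnames(background)))
    background <- background[, colnames(presence), drop = FALSE]
  presence <- presence[!duplicated(presence), , drop = FALSE]
  land <- rbind(presence, background)
  dup <- duplicated(land)
  land <- land[!dup, , drop = FALSE]
  m <- nrow(presence)
  is_pres <- seq_len(nrow(land)) <= m
  if (any(!is.finite(land))) stop("non-finite environmental values")

  fs <- build_features(land, classes = classes,
                       n_hinge_knots = n_hinge_knots)
  F <- fs$F
  n <- nrow(F); J <- ncol(F)
  pbar <- colMeans(F[is_pres, , drop = FALSE])
  s_pres <- apply(F[is_pres, , drop = FALSE], 2, stats::sd)
  if (m == 1) s_pres[] <- 0
  cls <- fs$spec$table$class
  beta <- reg_multiplier * unname(class_beta[cls]) * s_pres / sqrt(m)

  lambda <- numeric(J)
  eta <- numeric(n)
  gain <- 0
  obj <- function(eta, lambda)
    sum(eta[is_pres]) / m - logsumexp(eta) + log(n) -
      sum(beta * abs(lambda))
  trace_feat <- integer(0); trace_delta <- numeric(0)
  gain_path <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (cycle in seq_len(max_iter)) {
    iter <- cycle
    gain_prev <- gain
    for (j in seq_len(J)) {
      fj <- F[, j]
      w <- exp(eta - max(eta)); q <- w / sum(w)
      Ef <- sum(q * fj)
      Vf <- max(sum(q * fj^2) - Ef^2, 1e-12)
      g <- pbar[j] - Ef
      u <- lambda[j] + g / Vf
      lam_new <- sign(u) * max(abs(u) - beta[j] / Vf, 0)
      if (lam_new == lambda[j]) next
      # exact backtracking on the concave objective
      step <- lam_new - lambda[j]
      accepted <- FALSE
      for (t in 0:20) {
        cand <- lambda[j] + step * 2^(-t)
        eta_c <- eta + (cand - lambda[j]) * fj
        lam_c <- lambda; lam_c[j] <- cand
        g_c <- obj(eta_c, lam_c)
        if (g_c >= gain - 1e-12) {
          if (g_c > gain) {
            trace_feat <- c(trace_feat, j)
            trace_delta <- c(trace_delta, g_c - gain)
          }
          lambda[j] <- cand; eta <- eta_c; gain <- g_c
          accepted <- TRUE
          break
        }
      }
      if (!accepted) next
    }
    gain_path <- c(gain_path, gain)
    if (abs(gain - gain_prev) < tol * max(1, abs(gain))) {
      converged <- TRUE
      break
    }
  }
  logZ <- logsumexp(eta)
  q <- exp(eta - logZ)
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  train_auc <- if (any(!is_pres))
    suppressWarnings(auc(q[is_pres], q[!is_pres])) else NA_real_
  names(lambda) <- colnames(F)
  names(beta) <- colnames(F)
  structure(list(
    lambda = lambda, beta = beta, reg_multiplier = reg_multiplier,
    features = fs$spec, logZ = logZ, H = H,
    variables = names(fs$spec$normalization$lo),
    training = list(gain = gain, train_auc = train_auc,
                    n_presence = m, n_background = nrow(background),
                    n_landscape = n, max_iter = max_iter, tol = tol,
                    iterations = iter, converged = converged),
    trace = data.frame(feature = trace_feat, gain_delta = trace_delta),
    gain_path = gain_path,
    presence = presence, background = land[!is_pres, , drop = FALSE],
    settings = list(classes = fs$classes, n_hinge_knots = n_hinge_knots,
                    class_beta = class_beta)),
    class = "maxent")
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("Maximum-entropy suitability model (%d presences, %d background cells)\n",
              x$training$n_presence, x$training$n_background))
  cat(sprintf("  features: %d (%s); reg multiplier %g\n",
              length(x$lambda), paste(x$settings$classes, collapse = "+"),
              x$reg_multiplier))
  cat(sprintf("  training gain %.4f, training AUC %.4f, %d/%d iterations%s\n",
              x$training$gain, x$training$train_auc, x$training$iterations,
              x$training$max_iter,
              if (x$training$converged) " (converged)" else ""))
  invisible(x)
}

#' @export
summary.maxent <- function(object, n_top = 10, ...) {
  lam <- object$lambda
  active <- sum(lam != 0)
  top <- sort(abs(lam), decreasing = TRUE)
  top <- lam[names(top)[seq_len(min(n_top, length(top)))]]
  out <- list(model = object, n_active = active, top_weights = top,
              contributions = percent_contribution(object))
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  cat(sprintf("  active features: %d of %d\n", x$n_active,
              length(x$model$lambda)))
  cat("  largest weights:\n")
  print(round(x$top_weights, 4))
  cat("  percent contribution by variable:\n")
  print(round(x$contributions, 1))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambda

#' Predict suitability from a fitted model
#'
#' Evaluates the model on new environmental data, clamping each
#' variable to its training range. `raw` gives the normalized density
#' `q(x) = exp(lambda . f(x) - logZ)` (sums to 1 over the training
#' landscape sample); `cloglog` gives the suitability transform
#' `1 - exp(-exp(H) * q(x))` in `[0, 1]`, with `H` the entropy of the
#' fitted distribution.
#'
#' @param object a fitted [maxent()] model.
#' @param newdata matrix/data.frame of environmental values, or an
#'   [env_stack()] (then a `suitability_map` is returned with nodata
#'   propagated).
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param ... unused.
#' @return numeric vector, or a `suitability_map` for stack input.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("cloglog", "raw"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "env_stack")) {
    vals <- rep(NA_real_, n_cells(newdata$grid))
    ok <- which(!newdata$nodata_mask)
    X <- stack_values(newdata, ok, intersect(names(newdata$layers),
                                             unique(c(object$features$table$var1,
                                                      stats::na.omit(object$features$table$var2)))))
    vals[ok] <- predict(object, X, type = type)
    return(suitability_map(newdata$grid, vals, transform = type,
                           scenario = newdata$scenario))
  }
  X <- as.matrix(newdata)
  fs <- eval_features(X, object$features)
  eta <- as.vector(fs$F %*% object$lambda)
  raw <- exp(eta - object$logZ)
  if (type == "raw") raw else 1 - exp(-exp(object$H) * raw)
}

#' A per-cell suitability surface
#'
#' @param grid a [grid_spec()].
#' @param values per-cell suitability, row-major, `NA` at nodata.
#' @param transform `"cloglog"` or `"raw"`.
#' @param scenario scenario label.
#' @param model_id optional model reference label.
#' @return object of class `suitability_map`.
#' @export
suitability_map <- function(grid, values, transform = "cloglog",
                            scenario = "current", model_id = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"), length(values) == n_cells(grid))
  structure(list(grid = grid, values = values, transform = transform,
                 scenario = scenario, model_id = model_id),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s (%s), %d x %d grid, range [%.3f, %.3f]\n",
              x$scenario, x$transform, x$grid$n_rows, x$grid$n_cols,
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Ranking AUC of presence versus background scores
#'
#' The probability that a random presence is ranked above a random
#' background cell: the Mann-Whitney statistic `U/(m*n)` with midrank
#' tie handling.
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  if (m == 0 || n == 0) stop("both score sets must be non-empty")
  all_s <- c(presence_scores, background_scores)
  if (length(unique(all_s)) == 1) {
    warning("all scores identical; AUC degenerate")
    return(0.5)
  }
  r <- rank(all_s)  # midranks
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Serialize a fitted model to JSON
#'
#' @param object a [maxent()] model.
#' @param path output path.
#' @export
write_maxent_json <- function(object, path) {
  out <- list(
    lambda = as.list(object$lambda), beta = as.list(object$beta),
    reg_multiplier = object$reg_multiplier,
    features = object$features$table,
    normalization = list(lo = as.list(object$features$normalization$lo),
                         hi = as.list(object$features$normalization$hi)),
    logZ = object$logZ, H = object$H,
    training = object$training, settings = object$settings[c("classes",
                                                             "n_hinge_knots")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
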