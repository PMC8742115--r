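# Independent oracles the unit tests compare the implementation against.
# Each one recomputes the target quantity by a different route (explicit
# projection, exhaustive enumeration, 1-D numerical optimization).

# RM coefficient via the explicit data-space projection: standardized
# data X, orthogonal projection onto the span of the subset columns.
rm_data_space <- function(X, subset) {
  Xs <- scale(X)
  Xk <- Xs[, subset, drop = FALSE]
  P <- Xk %*% solve(crossprod(Xk)) %*% t(Xk)
  sqrt(sum(diag(crossprod(Xs, P %*% Xs))) / sum(Xs^2))
}

# AUC by exhaustive pair enumeration (ties count one half).
auc_enumeration <- function(pres, bg) {
  tot <- 0
  for (p in pres) for (b in bg)
    tot <- tot + (p > b) + 0.5 * (p == b)
  tot / (length(pres) * length(bg))
}

# Brute-force 1-D regularized maxent: maximize
#   mean_pres(lambda*f) - log mean_land exp(lambda*f) - beta*|lambda|
# by golden-section search through optimize().
maxent_1d_oracle <- function(f_land, is_pres, beta = 0, bounds = c(-60, 60)) {
  obj <- function(lam)
    mean(lam * f_land[is_pres]) -
      (log(sum(exp(lam * f_land - max(lam * f_land, 0)))) +
         max(lam * f_land, 0) - log(length(f_land))) -
      beta * abs(lam)
  op <- stats::optimize(obj, bounds, maximum = TRUE, tol = 1e-10)
  list(lambda = op$maximum, gain = op$objective)
}

# Small raw-data fixture: n cells of p standard-normal variables with
# column names, reproducible.
random_env_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", seq_len(p))))
}

# A tiny planar stack built in code (values row-major from the NW).
toy_stack <- function(values_list, n_rows, n_cols, cell = 1000,
                      scenario = "synthetic-toy") {
  g <- grid_spec(n_rows, n_cols, origin_x = 0, origin_y = n_rows * cell,
                 cell_size_x = cell, cell_size_y = cell,
                 crs_tag = "synthetic-planar")
  env_stack(g, values_list, scenario = scenario)
}

# The standard recovery benchmark plus its full fit, computed once per
# test run and cached for every file that needs it.
benchmark_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- synthetic_benchmark(42)
      fit <- maxent(b$presence_data, b$background_data)
      cache <<- list(bench = b, fit = fit)
    }
    cache
  }
})
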