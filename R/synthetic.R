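# Gaussian-kernel smoothing matrix for one axis, rows renormalized so
# edge cells average over the available neighbourhood only.
smooth_matrix <- function(n, width) {
  if (width <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
  K <- exp(-d / (2 * width^2))
  K / rowSums(K)
}

#' Simulate correlated, spatially smooth environmental fields
#'
#' White-noise fields are smoothed with a Gaussian kernel (inducing
#' spatial autocorrelation), standardized, mixed across variables by
#' the Cholesky factor of the target correlation matrix, and affinely
#' mapped onto plausible climate ranges.
#'
#' @param grid a [grid_spec()]; the default is a 64 x 64 geographic
#'   grid of 0.01 degree (~1 km) cells over a western-Mediterranean
#'   style extent.
#' @param var_names layer names.
#' @param correlation target cross-variable correlation matrix
#'   (default identity); must be positive semi-definite.
#' @param smoothness Gaussian kernel width in cells (0 = pure mixed
#'   white noise).
#' @param means,sds per-variable affine mapping onto climate-like
#'   units.
#' @param seed integer seed.
#' @param scenario scenario label of the stack.
#' @return an [env_stack()].
#' @export
simulate_env <- function(grid = synthetic_grid(),
                         var_names = c("BIO1", "BIO9", "BIO16", "BIO11",
                                       "BIO15", "slope"),
                         correlation = NULL, smoothness = 3,
                         means = NULL, sds = NULL, seed = 1,
                         scenario = "synthetic-current") {
  p <- length(var_names)
  if (p < 2) stop("need at least 2 variables")
  if (is.null(correlation)) correlation <- diag(p)
  stopifnot(nrow(correlation) == p, ncol(correlation) == p)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("correlation matrix is not positive semi-definite")
  if (is.null(means)) means <- rep(0, p)
  if (is.null(sds)) sds <- rep(1, p)
  nr <- grid$n_rows; ncl <- grid$n_cols
  set.seed(seed)
  Z <- matrix(stats::rnorm(nr * ncl * p), ncol = p)
  Kr <- smooth_matrix(nr, smoothness)
  Kc <- smooth_matrix(ncl, smoothness)
  for (j in seq_len(p)) {
    M <- matrix(Z[, j], nrow = nr, byrow = TRUE)
    M <- Kr %*% M %*% t(Kc)
    Z[, j] <- as.vector(t(M))
  }
  Z <- scale(Z)  # standardize each smoothed field
  U <- chol(correlation + diag(1e-10, p))
  X <- Z %*% U
  layers <- stats::setNames(vector("list", p), var_names)
  for (j in seq_len(p)) layers[[var_names[j]]] <- X[, j] * sds[j] + means[j]
  env_stack(grid, layers, scenario = scenario)
}

#' Default synthetic analysis grid
#'
#' A 64 x 64 geographic grid of 0.01-degree cells (about 1 km at these
#' latitudes) over a western-Mediterranean style extent.
#'
#' @param n_rows,n_cols grid dimensions.
#' @return a [grid_spec()].
#' @export
synthetic_grid <- function(n_rows = 64, n_cols = 64) {
  grid_spec(n_rows, n_cols, origin_x = -9.0, origin_y = 43.0,
            cell_size_x = 0.01, cell_size_y = 0.01,
            crs_tag = "geographic-WGS84")
}

#' Apply an additive/multiplicative climate shift to a stack
#'
#' Each shifted layer becomes `layer * scale + offset`; unshifted
#' layers are copied unchanged. The default shifts of
#' [default_scenario_shifts()] emulate the direction of change the
#' climate scenarios impose: temperatures (BIO1, BIO9) warming and
#' wet-season precipitation (BIO16) drying from past to future.
#'
#' @param stack an [env_stack()].
#' @param shifts named list: per layer either `c(offset)` or
#'   `c(offset, scale)`.
#' @param label scenario label of the shifted stack.
#' @return an [env_stack()].
#' @export
apply_scenario_shift <- function(stack, shifts, label) {
  unknown <- setdiff(names(shifts), names(stack$layers))
  if (length(unknown) > 0)
    stop(sprintf("shift names unknown in stack: %s",
                 paste(unknown, collapse = ", ")))
  layers <- stack$layers
  for (v in names(shifts)) {
    sh <- shifts[[v]]
    offset <- sh[1]
    scale <- if (length(sh) > 1) sh[2] else 1
    layers[[v]] <- layers[[v]] * scale + offset
  }
  env_stack(stack$grid, layers, scenario = label,
            nodata_mask = stack$nodata_mask)
}

#' Default synthetic scenario shifts
#'
#' Six scenarios mirroring a palaeo/future study design: two cooler,
#' wetter past scenarios and four progressively warmer, drier future
#' ones. Offsets are in the variables' own units (degrees C for BIO1
#' and BIO9, mm for BIO16).
#'
#' @return named list of shift lists, one per scenario label.
#' @export
default_scenario_shifts <- function() {
  list(
    "synthetic-LGM"       = list(BIO1 = -5.0, BIO9 = -5.5, BIO16 = 60),
    "synthetic-MH"        = list(BIO1 = -1.5, BIO9 = -1.6, BIO16 = 20),
    "synthetic-RCP45-2050" = list(BIO1 = 1.5, BIO9 = 1.8, BIO16 = -40),
    "synthetic-RCP45-2070" = list(BIO1 = 2.2, BIO9 = 2.6, BIO16 = -60),
    "synthetic-RCP85-2050" = list(BIO1 = 2.5, BIO9 = 3.0, BIO16 = -70),
    "synthetic-RCP85-2070" = list(BIO1 = 4.0, BIO9 = 4.8, BIO16 = -110))
}

#' Define a known niche truth
#'
#' The true suitability is a unimodal (Gaussian-on-the-logit-scale)
#' niche over the informative variables:
#' `s(x) = plogis(a0 - sum_j ((v_j - opt_j) / tol_j)^2)`.
#'
#' @param response named list: per informative variable
#'   `c(optimum, tolerance)` (tolerance > 0, in the variable's units).
#' @param a0 logit-scale intercept; controls overall prevalence (see
#'   [calibrate_intercept()]).
#' @param prevalence target mean suitability the intercept was (or is
#'   to be) calibrated to.
#' @param seeds named integer vector of the seeds used downstream
#'   (recorded for reproducibility).
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(response, a0 = 0, prevalence = NA_real_,
                            seeds = c(field = NA, presence = NA,
                                      background = NA)) {
  for (v in names(response)) {
    if (response[[v]][2] <= 0)
      stop(sprintf("zero or negative tolerance for '%s'", v))
  }
  structure(list(response = response,
                 informative_vars = names(response),
                 a0 = a0, prevalence = prevalence, seeds = seeds),
            class = "synthetic_truth")
}

#' True suitability of a stack under a known niche
#'
#' @param stack an [env_stack()] containing the informative variables.
#' @param truth a [synthetic_truth()].
#' @return a [suitability_map()] (transform `"truth"`).
#' @export
true_suitability <- function(stack, truth) {
  miss <- setdiff(truth$informative_vars, names(stack$layers))
  if (length(miss) > 0)
    stop(sprintf("informative variable(s) missing: %s",
                 paste(miss, collapse = ", ")))
  lin <- rep(truth$a0, n_cells(stack$grid))
  for (v in truth$informative_vars) {
    opt <- truth$response[[v]][1]; tol <- truth$response[[v]][2]
    lin <- lin - ((stack$layers[[v]] - opt) / tol)^2
  }
  vals <- stats::plogis(lin)
  vals[stack$nodata_mask] <- NA
  suitability_map(stack$grid, vals, transform = "truth",
                  scenario = stack$scenario)
}

#' Calibrate the niche intercept to a target prevalence
#'
#' Finds `a0` such that the landscape-mean true suitability equals the
#' target prevalence (monotone in `a0`, solved by [stats::uniroot()]).
#'
#' @param stack an [env_stack()].
#' @param truth a [synthetic_truth()] (its `a0` is ignored).
#' @param prevalence target mean suitability in (0, 1).
#' @return the calibrated `synthetic_truth`.
#' @export
calibrate_intercept <- function(stack, truth, prevalence = 0.15) {
  stopifnot(prevalence > 0, prevalence < 1)
  f <- function(a0) {
    t2 <- truth; t2$a0 <- a0
    mean(true_suitability(stack, t2)$values, na.rm = TRUE) - prevalence
  }
  a0 <- stats::uniroot(f, c(-30, 30), tol = 1e-6)$root
  truth$a0 <- a0
  truth$prevalence <- prevalence
  truth
}

#' Sample presence records proportional to true suitability
#'
#' Cells are drawn without replacement with probability proportional
#' to true suitability and converted to cell-center coordinates; the
#' sample is one-per-cell by construction.
#'
#' @param truth_map a [true_suitability()] map.
#' @param n_target number of presences.
#' @param seed integer seed.
#' @return an [occurrence_set()] with a `cell` column.
#' @export
sample_presences <- function(truth_map, n_target, seed = 1) {
  s <- truth_map$values
  ok <- which(!is.na(s) & s > 0)
  if (length(ok) == 0) stop("true suitability is zero everywhere")
  if (n_target > length(ok))
    stop("n_target exceeds the number of cells with positive suitability")
  set.seed(seed)
  cells <- sample(ok, n_target, prob = s[ok])
  ctr <- cell_centers(truth_map$grid, cells)
  occ <- occurrence_set(ctr$x, ctr$y, source = "synthetic")
  occ$cell <- cells
  occ
}

#' The package's standard synthetic recovery benchmark
#'
#' One call builds the full study-in-miniature used throughout the
#' test-suite: a 64 x 64 grid with 6 correlated environmental fields
#' (3 informative — BIO1, BIO9, BIO16; one decoy, BIO11, correlated
#' 0.85 with BIO1 but outside the niche; 2 pure-noise fields, BIO15
#' and slope), a unimodal niche truth calibrated to 15% prevalence,
#' 500 presence cells drawn proportional to true suitability and a
#' 2,000-cell background sample.
#'
#' @param seed base integer seed; the field, presence and background
#'   seeds are derived from it.
#' @return list: `stack`, `truth`, `truth_map`, `occurrences`,
#'   `background_cells`, `presence_data`, `background_data`.
#' @export
synthetic_benchmark <- function(seed = 42) {
  vars <- c("BIO1", "BIO9", "BIO16", "BIO11", "BIO15", "slope")
  C <- diag(6)
  dimnames(C) <- list(vars, vars)
  C["BIO1", "BIO9"] <- C["BIO9", "BIO1"] <- 0.6
  C["BIO1", "BIO11"] <- C["BIO11", "BIO1"] <- 0.85
  C["BIO9", "BIO11"] <- C["BIO11", "BIO9"] <- 0.5
  stack <- simulate_env(
    grid = synthetic_grid(), var_names = vars, correlation = C,
    smoothness = 3,
    means = c(12, 18, 400, 5, 40, 8), sds = c(5, 6, 150, 5, 12, 6),
    seed = seed, scenario = "synthetic-current")
  truth <- synthetic_truth(
    response = list(BIO1 = c(14, 4), BIO9 = c(22, 5), BIO16 = c(450, 180)),
    seeds = c(field = seed, presence = seed + 1, background = seed + 2))
  truth <- calibrate_intercept(stack, truth, prevalence = 0.15)
  tmap <- true_suitability(stack, truth)
  occ <- sample_presences(tmap, 500, seed = seed + 1)
  bg <- sample_background(stack, 2000, seed = seed + 2)
  list(stack = stack, truth = truth, truth_map = tmap,
       occurrences = occ, background_cells = bg,
       presence_data = stack_values(stack, occ$cell),
       background_data = stack_values(stack, bg))
}
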