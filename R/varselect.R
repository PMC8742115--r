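#' Background correlation matrix of environmental layers
#'
#' Pearson correlations among layers over a random background sample of
#' unmasked cells. Constant layers cannot enter a correlation matrix
#' and are excluded with a warning.
#'
#' @param stack an [env_stack()].
#' @param n_sample number of background cells to sample (sampled
#'   without replacement; capped at the number of unmasked cells with a
#'   warning).
#' @param seed integer seed for the cell sample.
#' @return list of class `correlation_matrix`: `variables`, `R`,
#'   `n_background_sampled`, `seed`.
#' @export
background_correlation <- function(stack, n_sample = 1e5, seed = 1) {
  cells <- which(!stack$nodata_mask)
  if (n_sample > length(cells)) {
    warning("n_sample exceeds unmasked cells; using all of them")
    n_sample <- length(cells)
  }
  set.seed(seed)
  samp <- sample(cells, n_sample)
  X <- stack_values(stack, samp)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding constant layer(s): %s",
                    paste(colnames(X)[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 2) stop("fewer than 2 usable variables")
  structure(list(variables = colnames(X), R = stats::cor(X),
                 n_background_sampled = n_sample, seed = seed),
            class = "correlation_matrix")
}

as_correlation_matrix <- function(R) {
  if (inherits(R, "correlation_matrix")) return(R)
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (is.null(colnames(R))) colnames(R) <- rownames(R) <-
      paste0("V", seq_len(ncol(R)))
  structure(list(variables = colnames(R), R = R,
                 n_background_sampled = NA_integer_, seed = NA_integer_),
            class = "correlation_matrix")
}

#' RM matrix-correlation of a variable subset
#'
#' The RM coefficient of subset K is the matrix correlation between the
#' standardized data and its orthogonal projection onto the span of the
#' K variables. It only needs the correlation matrix:
#' `RM = sqrt( tr(R[,K] solve(R[K,K]) R[K,]) / p )`, i.e. the root mean
#' squared multiple correlation of every variable on the subset. It is
#' 1 for the full set and monotone non-decreasing as K grows.
#'
#' @param R a correlation matrix (plain matrix or
#'   [background_correlation()] result).
#' @param subset variable names or column indices of the subset K.
#' @return RM value in `[0, 1]`.
#' @export
rm_coefficient <- function(R, subset) {
  cm <- as_correlation_matrix(R)
  p <- length(cm$variables)
  if (length(subset) == 0) stop("empty subset")
  if (is.character(subset)) subset <- match(subset, cm$variables)
  if (anyNA(subset)) stop("subset contains unknown variables")
  Rm <- cm$R
  Rkk <- Rm[subset, subset, drop = FALSE]
  Rak <- Rm[, subset, drop = FALSE]
  inv <- tryCatch(solve(Rkk), error = function(e) NULL)
  if (is.null(inv) || rcond(Rkk) < 1e-12) {
    warning("near-singular subset correlation; ridge-regularizing")
    inv <- solve(Rkk + diag(1e-10, nrow(Rkk)))
  }
  val <- sum(diag(Rak %*% inv %*% t(Rak))) / p
  sqrt(min(max(val, 0), 1))
}

#' Select the best k-variable subset by the RM criterion
#'
#' Exhaustive mode enumerates all `choose(p, k)` subsets (refused above
#' 1e6 subsets); greedy mode grows the subset by the best marginal RM
#' gain. Ties are broken by variable-name order.
#'
#' @param R correlation matrix (plain matrix or
#'   [background_correlation()] result).
#' @param k subset size, `1 <= k < p`.
#' @param mode `"exhaustive"` or `"greedy"`; `"auto"` picks exhaustive
#'   when the enumeration fits under the guard.
#' @return list of class `subset_result`: `subset` (names), `rm_value`,
#'   `search_mode`, `n_background_sampled`, `seed`.
#' @export
select_subset <- function(R, k, mode = c("auto", "exhaustive", "greedy")) {
  cm <- as_correlation_matrix(R)
  mode <- match.arg(mode)
  p <- length(cm$variables)
  if (k < 1 || k >= p) stop("k must satisfy 1 <= k < p")
  if (mode == "auto")
    mode <- if (choose(p, k) <= 1e6) "exhaustive" else "greedy"
  ord <- order(cm$variables)  # name order for tie-breaks
  if (mode == "exhaustive") {
    if (choose(p, k) > 1e6) stop("enumeration too large; use greedy mode")
    combos <- utils::combn(ord, k, simplify = FALSE)
    vals <- vapply(combos, function(s) rm_coefficient(cm, s), numeric(1))
    best <- combos[[which.max(vals)]]  # first max = earliest in name order
    rmv <- max(vals)
  } else {
    chosen <- integer(0)
    for (step in seq_len(k)) {
      cand <- setdiff(ord, chosen)
      vals <- vapply(cand, function(j) rm_coefficient(cm, c(chosen, j)),
                     numeric(1))
      chosen <- c(chosen, cand[which.max(vals)])
      rmv <- max(vals)
    }
    best <- chosen
  }
  structure(list(subset = cm$variables[sort(best)], rm_value = rmv,
                 search_mode = mode,
                 n_background_sampled = cm$n_background_sampled,
                 seed = cm$seed),
            class = "subset_result")
}

#' @export
print.subset_result <- function(x, ...) {
  cat(sprintf("<subset_result> %d variable(s), RM = %.5f (%s search)\n",
              length(x$subset), x$rm_value, x$search_mode))
  cat(" ", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' Write a subset-selection report
#'
#' @param result a [select_subset()] result.
#' @param path CSV output path.
#' @export
write_subset_report <- function(result, path) {
  utils::write.csv(
    data.frame(variable = result$subset, rm_value = result$rm_value,
               search_mode = result$search_mode,
               n_background_sampled = result$n_background_sampled,
               seed = result$seed),
    path, row.names = FALSE)
  invisible(path)
}
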