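test_that("background sampling is uniform, exhaustive at n = N, reproducible", {
  st <- toy_stack(list(v = rnorm(25), w = rnorm(25)), 5, 5)
  expect_equal(suppressWarnings(sample_background(st, 25, seed = 1)), 1:25)
  expect_identical(sample_background(st, 5, seed = 9),
                   sample_background(st, 5, seed = 9))
  # frequency of cell 1 over 1000 seeds within binomial 99% bounds
  hits <- sum(vapply(1:1000, function(s) 1L %in% sample_background(st, 5, s),
                     logical(1)))
  p <- 5 / 25
  expect_true(abs(hits - 1000 * p) < 2.576 * sqrt(1000 * p * (1 - p)))
  st_masked <- env_stack(st$grid, st$layers,
                         nodata_mask = rep(TRUE, 25))
  expect_error(sample_background(st_masked, 5), "masked")
})

test_that("feature expansion has the expected columns and endpoint identities", {
  X <- cbind(a = c(0, 0.25, 0.5, 1), b = c(2, 4, 6, 8))
  fs <- build_features(X, classes = "linear")
  expect_equal(ncol(fs$F), 1 + 1)
  expect_equal(fs$F[, "a"], c(0, 0.25, 0.5, 1))  # min-max scaling

  fs2 <- build_features(X, classes = c("linear", "quadratic", "product"))
  expect_equal(ncol(fs2$F), 2 + 2 + 1)           # p + p + choose(p,2)

  # forward hinge: 0 at the knot, 1 at the training max
  set.seed(1)
  X3 <- cbind(v = runif(200))
  fs3 <- build_features(X3, classes = "hinge", n_hinge_knots = 4)
  tab <- fs3$spec$table
  fwd <- which(tab$orientation == "forward")[1]
  k <- tab$knot[fwd]
  lo <- fs3$normalization$lo["v"]; hi <- fs3$normalization$hi["v"]
  at <- maxsuit:::eval_features(cbind(v = c(lo + k * (hi - lo), hi)), fs3$spec)
  expect_equal(unname(at$F[1, fwd]), 0)
  expect_equal(unname(at$F[2, fwd]), 1)

  expect_warning(build_features(cbind(a = rep(1, 4), b = 1:4)),
                 "zero-variance")
})

test_that("projection clamps to the training range", {
  X <- cbind(a = c(0, 1, 2, 3, 4))
  fs <- build_features(X, classes = "linear")
  out <- maxsuit:::eval_features(cbind(a = c(-10, 4.5)), fs$spec)
  expect_equal(out$F[, 1], c(0, 1))
})

test_that("matched presence and landscape means give the null model", {
  # presences environmentally indistinguishable from the landscape
  X <- cbind(v = rep(c(1, 2, 3, 4), 25))
  fit <- maxent(X[1:4, , drop = FALSE], X, classes = "linear",
                reg_multiplier = 0)
  expect_equal(unname(fit$lambda), 0)
  expect_equal(fit$training$gain, 0)
})

test_that("beta = 0 linear fits match presence means (moment matching)", {
  set.seed(21)
  land <- cbind(x = c(0, 1, runif(198)), y = c(0, 1, runif(198)))
  pres <- land[land[, "x"] > 0.6, ]
  fit <- maxent(pres, land, classes = "linear", reg_multiplier = 0,
                tol = 1e-10, max_iter = 5000)
  fs <- maxsuit:::eval_features(rbind(fit$presence, fit$background),
                                fit$features)
  eta <- as.vector(fs$F %*% fit$lambda)
  q <- exp(eta - maxsuit:::logsumexp(eta))
  Ef <- colSums(q * fs$F)
  pbar <- colMeans(maxsuit:::eval_features(fit$presence, fit$features)$F)
  expect_equal(unname(Ef), unname(pbar), tolerance = 1e-4)
})

test_that("single-feature fits match the brute-force 1-D solver", {
  set.seed(31)
  v <- c(0, 1, runif(118))
  land <- cbind(v = v)
  pres <- land[v > 0.5, , drop = FALSE]
  for (beta_mult in c(0, 1)) {
    fit <- maxent(pres, land, classes = "linear",
                  reg_multiplier = beta_mult, tol = 1e-12, max_iter = 1e4)
    f_land <- maxsuit:::eval_features(rbind(fit$presence, fit$background),
                                      fit$features)$F[, 1]
    m <- fit$training$n_presence
    oracle <- maxent_1d_oracle(f_land, seq_along(f_land) <= m,
                               beta = unname(fit$beta))
    expect_equal(unname(fit$lambda), oracle$lambda, tolerance = 1e-4)
    expect_equal(fit$training$gain, oracle$gain, tolerance = 1e-6)
  }
})

test_that("a perfectly separating binary feature approaches gain log 2", {
  land <- cbind(v = rep(c(0, 1), each = 50))
  pres <- cbind(v = rep(1, 10))
  fit <- maxent(pres, land, classes = "linear", reg_multiplier = 0,
                tol = 1e-9, max_iter = 5000)
  fs <- maxsuit:::eval_features(rbind(fit$presence, fit$background),
                                fit$features)
  eta <- as.vector(fs$F %*% fit$lambda)
  q <- exp(eta - maxsuit:::logsumexp(eta))
  expect_gt(sum(q * fs$F[, 1]), 0.99)           # E_q[f] -> 1
  expect_equal(fit$training$gain, log(2), tolerance = 1e-3)
})

test_that("converged fits satisfy the KKT box condition", {
  bf <- benchmark_fit()
  fit <- bf$fit
  fs <- maxsuit:::eval_features(rbind(fit$presence, fit$background),
                                fit$features)
  eta <- as.vector(fs$F %*% fit$lambda)
  q <- exp(eta - maxsuit:::logsumexp(eta))
  Ef <- colSums(q * fs$F)
  pbar <- colMeans(fs$F[seq_len(fit$training$n_presence), , drop = FALSE])
  expect_true(all(abs(Ef - pbar) <= fit$beta + 1e-3))
})

test_that("gain is monotone over iterations and raw scores normalize", {
  bf <- benchmark_fit()
  fit <- bf$fit
  expect_true(all(diff(fit$gain_path) >= -1e-12))
  raw <- predict(fit, rbind(fit$presence, fit$background), type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
})

test_that("doubling the regularization never grows the L1 norm", {
  set.seed(41)
  b <- synthetic_benchmark(7)
  pres <- b$presence_data[1:120, ]; bg <- b$background_data[1:600, ]
  f1 <- maxent(pres, bg, reg_multiplier = 1)
  f2 <- maxent(pres, bg, reg_multiplier = 2)
  expect_lte(sum(abs(f2$lambda)), sum(abs(f1$lambda)) + 1e-8)
})

test_that("cloglog prediction: uniform closed form, clamping no-op, rank equality", {
  X <- cbind(v = rep(c(1, 2, 3, 4), 25))
  fit <- maxent(X[1:4, , drop = FALSE], X, classes = "linear",
                reg_multiplier = 0)
  # lambda = 0: q uniform over N cells, cloglog = 1 - exp(-1) everywhere
  p <- predict(fit, cbind(v = c(1.5, 3.3)), type = "cloglog")
  expect_equal(p, rep(1 - exp(-1), 2))

  bf <- benchmark_fit()
  fit2 <- bf$fit
  tr_scores <- predict(fit2, fit2$presence, type = "cloglog")
  again <- predict(fit2, fit2$presence, type = "cloglog")
  expect_identical(tr_scores, again)  # training cells: clamping is a no-op

  nd <- bf$bench$background_data[1:200, ]
  expect_equal(order(predict(fit2, nd, type = "raw")),
               order(predict(fit2, nd, type = "cloglog")))
})

test_that("prediction errors name a missing layer", {
  bf <- benchmark_fit()
  nd <- bf$bench$background_data[1:5, setdiff(colnames(bf$bench$background_data),
                                              "BIO9")]
  expect_error(predict(bf$fit, nd), "BIO9")
})

test_that("AUC matches exhaustive pair enumeration, including ties", {
  expect_equal(auc(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(auc(c(0.8, 0.5), c(0.5, 0.2)), 0.875)
  expect_equal(suppressWarnings(auc(c(0.3, 0.3), c(0.3, 0.3))), 0.5)
  set.seed(17)
  for (rep in 1:10) {
    m <- sample(1:50, 1); n <- sample(1:50, 1)
    pres <- sample(seq(0, 1, 0.05), m, replace = TRUE)
    bg <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    expect_equal(suppressWarnings(auc(pres, bg)),
                 auc_enumeration(pres, bg))
  }
})

test_that("model JSON serialization round-trips the weights", {
  bf <- benchmark_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(bf$fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unname(unlist(back$lambda)), unname(bf$fit$lambda),
               tolerance = 1e-12)
  expect_equal(back$H, bf$fit$H, tolerance = 1e-12)
})
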