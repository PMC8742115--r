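test_that("percent contribution: single variable gets all, columns normalize", {
  set.seed(3)
  land <- cbind(v = c(0, 1, runif(98)))
  pres <- land[land[, "v"] > 0.6, , drop = FALSE]
  fit <- maxent(pres, land, classes = "linear")
  pc <- percent_contribution(fit)
  expect_equal(unname(pc["v"]), 100)

  bf <- benchmark_fit()
  expect_equal(sum(percent_contribution(bf$fit)), 100, tolerance = 0.1)
})

test_that("percent contribution of an iid noise decoy stays small", {
  # strong driver + white-noise decoy, no spatial structure to alias
  set.seed(13)
  land <- cbind(driver = runif(1500), noise = runif(1500))
  keep <- runif(1500) < plogis(8 * (land[, "driver"] - 0.7))
  pres <- land[keep, , drop = FALSE]
  fit <- maxent(pres, land)
  pc <- percent_contribution(fit)
  expect_lt(unname(pc["noise"]), 5)
})

test_that("permutation importance: absent variable 0, single variable 100", {
  set.seed(3)
  land <- cbind(v = c(0, 1, runif(98)), dead = runif(100))
  pres <- land[land[, "v"] > 0.6, , drop = FALSE]
  fit <- maxent(pres, land, classes = "linear")
  # force 'dead' out of the model by zeroing its weight
  fit$lambda[names(fit$lambda) == "dead"] <- 0
  pi_ <- permutation_importance(fit, seed = 1)
  expect_equal(unname(pi_["v"]), 100, tolerance = 1e-9)

  land1 <- land[, "v", drop = FALSE]
  fit1 <- maxent(pres[, "v", drop = FALSE], land1, classes = "linear")
  expect_equal(unname(permutation_importance(fit1, seed = 1)["v"]), 100)
})

test_that("noise variables score below the true drivers on the benchmark", {
  bf <- benchmark_fit()
  pi_ <- permutation_importance(bf$fit, seed = 45)
  expect_lt(pi_["BIO15"], min(pi_[c("BIO1", "BIO9", "BIO16")]))
  expect_lt(pi_["slope"], min(pi_[c("BIO1", "BIO9", "BIO16")]))
  expect_lt(pi_["BIO15"], 5)
  expect_lt(pi_["slope"], 5)
})

test_that("jackknife: duplicated variable is redundant, dominant driver leads", {
  set.seed(23)
  b <- synthetic_benchmark(7)
  pres <- b$presence_data[1:150, c("BIO1", "BIO15")]
  bg <- b$background_data[1:800, c("BIO1", "BIO15")]
  pres <- cbind(pres, BIO1copy = pres[, "BIO1"])
  bg <- cbind(bg, BIO1copy = bg[, "BIO1"])
  fit <- maxent(pres, bg)
  jk <- jackknife(fit)
  expect_gt(jk$without_ratio[jk$variable == "BIO1"], 0.98)  # copy covers it

  bf <- benchmark_fit()
  jk2 <- jackknife(bf$fit)
  only <- setNames(jk2$only_ratio, jk2$variable)
  expect_true(names(which.max(only)) %in% c("BIO1", "BIO9", "BIO16"))
  expect_gt(max(only), max(only[c("BIO15", "slope")]))
})

test_that("refitting on fewer variables never beats the full gain", {
  bf <- benchmark_fit()
  fit <- bf$fit
  for (v in c("BIO1", "BIO15")) {
    sub <- maxsuit:::refit_on(fit, setdiff(fit$variables, v))
    expect_lte(sub$training$gain, fit$training$gain + 1e-6)
  }
})

test_that("metric ranks are permutations and the table is rank-ordered", {
  bf <- benchmark_fit()
  m <- variable_metrics(bf$fit, seed = 45)
  expect_equal(sum(m$percent_contribution), 100, tolerance = 0.1)
  expect_equal(sum(m$permutation_importance), 100, tolerance = 0.1)
  for (col in c("rank_contribution", "rank_permutation",
                "rank_jk_without", "rank_jk_only"))
    expect_equal(sort(m[[col]]), seq_len(nrow(m)), tolerance = 1e-12)
  expect_false(is.unsorted(m$aggregate_rank))
})

test_that("backward elimination respects the AUC floor and its degenerate ends", {
  bf <- benchmark_fit()
  m <- variable_metrics(bf$fit, seed = 45)

  red <- rank_and_reduce(bf$fit, m, auc_floor = 0.995)
  expect_true(all(c("BIO1", "BIO9", "BIO16") %in% red$selected))
  expect_gte(red$model$training$train_auc,
             0.995 * bf$fit$training$train_auc)

  red0 <- rank_and_reduce(bf$fit, m, auc_floor = 0)
  expect_length(red0$selected, 1)  # last variable standing

  expect_warning(redX <- rank_and_reduce(bf$fit, m, auc_floor = 1 + 1e-9),
                 "unreachable")
  expect_setequal(redX$selected, bf$fit$variables)
})

test_that("elimination outcome is invariant to variable input order", {
  bf <- benchmark_fit()
  b <- bf$bench
  perm <- c("BIO16", "slope", "BIO1", "BIO15", "BIO9", "BIO11")
  fitp <- maxent(b$presence_data[, perm], b$background_data[, perm])
  mp <- variable_metrics(fitp, seed = 45)
  redp <- rank_and_reduce(fitp, mp, auc_floor = 0.995)
  m <- variable_metrics(bf$fit, seed = 45)
  red <- rank_and_reduce(bf$fit, m, auc_floor = 0.995)
  expect_setequal(redp$selected, red$selected)
})

test_that("response curves: flat at the null model, monotone for one linear feature", {
  X <- cbind(v = rep(c(1, 2, 3, 4), 25))
  fit0 <- maxent(X[1:4, , drop = FALSE], X, classes = "linear",
                 reg_multiplier = 0)
  rc0 <- response_curve(fit0, "v", n_points = 21)
  expect_equal(rc0$suitability, rep(1 - exp(-1), 21))

  set.seed(3)
  land <- cbind(v = c(0, 1, runif(98)))
  pres <- land[land[, "v"] > 0.6, , drop = FALSE]
  fit <- maxent(pres, land, classes = "linear")
  rc <- response_curve(fit, "v", n_points = 50)
  expect_true(all(diff(rc$suitability) > 0))
  expect_error(response_curve(fit, "nope"), "nope")
})

test_that("response-curve peak recovers the true niche optimum", {
  bf <- benchmark_fit()
  rc <- response_curve(bf$fit, "BIO1", n_points = 201)
  peak <- rc$x[which.max(rc$suitability)]
  truth <- bf$bench$truth$response$BIO1
  expect_lt(abs(peak - truth[1]), 0.1 * diff(range(rc$x)))
})
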