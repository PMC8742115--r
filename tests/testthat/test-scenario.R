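test_that("suitability classification uses left-closed intervals, last closed", {
  v <- c(0, 0.19, 0.2, 0.45, 0.6, 0.79, 0.8, 1.0, NA)
  cls <- classify_suitability(v)
  expect_equal(as.character(cls),
               c("non-suitable", "non-suitable", "low", "general", "medium",
                 "medium", "high", "high", NA))
  expect_equal(as.character(unique(classify_suitability(rep(0.5, 10)))),
               "general")
  expect_error(classify_suitability(v, breaks = c(0, 0.5, 0.4, 1)),
               "increasing")
})

test_that("suitability deltas follow the direction convention", {
  g <- grid_spec(1, 3, 0, 1000, 1000, 1000, crs_tag = "synthetic-planar")
  past <- suitability_map(g, c(0.2, 0.5, 0.9), scenario = "LGM")
  cur <- suitability_map(g, c(0.7, 0.5, 0.4), scenario = "current")
  fut <- suitability_map(g, c(0.1, 0.5, 0.2), scenario = "RCP85-2070")

  d_past <- suitability_delta(past, cur, "past-to-current")
  expect_equal(d_past$delta, c(0.5, 0, -0.5))     # current - past
  d_fut <- suitability_delta(cur, fut, "current-to-future")
  expect_equal(d_fut$delta, c(-0.6, 0, -0.2))     # future - current

  ident <- suitability_delta(cur, cur, "current-to-future")
  expect_equal(ident$delta, c(0, 0, 0))

  g2 <- grid_spec(3, 1, 0, 3000, 1000, 1000, crs_tag = "synthetic-planar")
  expect_error(suitability_delta(past, suitability_map(g2, 1:3 / 10)),
               "grid mismatch")
})

test_that("change accounting reproduces a 9-cell hand enumeration", {
  g <- grid_spec(3, 3, 0, 3000, 1000, 1000, crs_tag = "equal-area-EPSG3035")
  cur <- suitability_map(g, c(0.05, 0.05, 0.05, 0.5, 0.5, 0.5,
                              0.7, 0.7, 0.7), scenario = "current")
  fut <- suitability_map(g, c(0.15, 0.15, 0.15, 0.4, 0.4, 0.4,
                              0.7, 0.7, 0.7), scenario = "RCP")
  dl <- suitability_delta(cur, fut, "current-to-future")
  ct <- change_accounting(cur, dl, cell_areas(g))
  # by hand: top row (class 0.03-0.1) expands by 3 x 1 km2, middle row
  # (class 0.4-0.6) contracts by 3 x 1 km2, bottom row (class >0.6)
  # unchanged -> neither column
  expect_equal(ct$C, c(0, 0, 0, 0.003, 0))
  expect_equal(ct$E, c(0.003, 0, 0, 0, 0))
  expect_equal(attr(ct, "total_C"), 0.003)
  expect_equal(attr(ct, "total_E"), 0.003)
  expect_equal(net_change(ct), 0)

  # all-zero delta: every column zero
  dl0 <- suitability_delta(cur, cur, "current-to-future")
  ct0 <- change_accounting(cur, dl0, cell_areas(g))
  expect_true(all(ct0$C == 0) && all(ct0$E == 0))

  # cells under the 0.03 floor are excluded entirely
  cur2 <- suitability_map(g, c(0.01, 0.01, 0.01, 0.5, 0.5, 0.5,
                               0.7, 0.7, 0.7))
  ct2 <- change_accounting(cur2, dl, cell_areas(g))
  expect_equal(sum(ct2$E), 0)
})

test_that("conservation and antisymmetry hold on random suitability pairs", {
  set.seed(8)
  g <- grid_spec(12, 12, 0, 12000, 1000, 1000,
                 crs_tag = "equal-area-EPSG3035")
  areas <- cell_areas(g)
  for (rep in 1:5) {
    a <- suitability_map(g, runif(144), scenario = "current")
    b <- suitability_map(g, runif(144), scenario = "x")
    dl <- suitability_delta(a, b, "current-to-future")
    ct <- change_accounting(a, dl, areas)
    # conservation: C + E + unchanged = total area with suitability >= 0.03
    eligible <- sum(areas[a$values >= 0.03])
    unchanged <- sum(areas[a$values >= 0.03 & dl$delta == 0])
    expect_equal((attr(ct, "total_C") + attr(ct, "total_E")) * 1e3 +
                   unchanged, eligible)
    # antisymmetry: swapping the pair negates deltas and swaps C with E
    dl_r <- suitability_delta(b, a, "current-to-future")
    expect_equal(dl_r$delta, -dl$delta)
    ct_r <- change_accounting(a, dl_r, areas)
    expect_equal(ct_r$C, ct$E)
    expect_equal(ct_r$E, ct$C)
  }
})

test_that("published fixture reproduces the reported net changes", {
  tabs <- published_change_tables()
  expect_equal(net_change(tabs[["LGM"]], unit = "1e6_km2"), 2.371)
  expect_equal(round(net_change(tabs[["MH"]], unit = "1e6_km2"), 2), 1.98)
  expect_equal(net_change(tabs[["RCP45-2050"]]), 202)
  expect_equal(net_change(tabs[["RCP45-2070"]]), 95)
  expect_equal(net_change(tabs[["RCP85-2050"]]), -80)
  expect_equal(net_change(tabs[["RCP85-2070"]]), -316)
  expect_equal(net_change(change_table(
    data.frame(class = "a", C = 5, E = 5))), 0)
})

test_that("fixture per-class sums match stated totals except the flagged row", {
  tabs <- published_change_tables()
  cons <- lapply(tabs, check_change_consistency)
  expect_true(all(vapply(cons, `[[`, logical(1), "C_consistent")))
  e_ok <- vapply(cons, `[[`, logical(1), "E_consistent")
  expect_false(e_ok[["LGM"]])       # known internal inconsistency, stored as-is
  expect_true(all(e_ok[names(e_ok) != "LGM"]))
  expect_equal(cons[["LGM"]]$E_gap, 2441 - 1841)
})

test_that("delta histograms conserve per-class areas across scenarios", {
  set.seed(9)
  g <- grid_spec(10, 10, 0, 10000, 1000, 1000,
                 crs_tag = "equal-area-EPSG3035")
  areas <- cell_areas(g)
  cur <- suitability_map(g, runif(100), scenario = "current")
  cls <- classify_suitability(cur)
  d1 <- suitability_delta(cur, suitability_map(g, runif(100)), "current-to-future")
  d0 <- suitability_delta(cur, cur, "current-to-future")

  h0 <- change_histogram(d0, cls, areas, n_bins = 10)
  zero_bin <- which(h0$bin_lo <= 0 & h0$bin_hi > 0)
  expect_equal(sum(h0$total), sum(h0[zero_bin, "total"]))  # all mass at 0

  h1 <- change_histogram(d1, cls, areas, n_bins = 10)
  for (lv in levels(droplevels(cls))) {
    expect_equal(sum(h1[[lv]]), sum(areas[!is.na(cls) & cls == lv]))
    expect_equal(sum(h1[[lv]]), sum(h0[[lv]]))  # bands equal across scenarios
  }
  expect_error(change_histogram(d1, cls, areas, n_bins = 1), "n_bins")
})

test_that("variable shift summaries recover imposed offsets", {
  set.seed(10)
  st <- toy_stack(list(BIO1 = rnorm(100, 12), BIO16 = rnorm(100, 400)),
                  10, 10, scenario = "synthetic-current")
  sh <- apply_scenario_shift(st, list(BIO1 = 2), "synthetic-warm")
  ss <- variable_shift_summary(st, sh)
  r1 <- ss[ss$variable == "BIO1" & ss$domain == "area", ]
  expect_equal(unlist(r1[, c("q05", "q25", "q50", "q75", "q95")]),
               rep(2, 5), ignore_attr = TRUE)
  r2 <- ss[ss$variable == "BIO16" & ss$domain == "area", ]
  expect_equal(unname(unlist(r2[, 3:7])), rep(0, 5))

  # occurrence subset of a uniform shift equals the area summary
  occ <- data.frame(cell = maxsuit:::cell_index(st$grid, c(500, 5500),
                                                c(9500, 500)))
  ss2 <- variable_shift_summary(st, sh, occ)
  a <- ss2[ss2$variable == "BIO1" & ss2$domain == "area", 3:7]
  o <- ss2[ss2$variable == "BIO1" & ss2$domain == "occurrences", 3:7]
  expect_equal(unname(unlist(a)), unname(unlist(o)))

  # spatially confined drying: occurrences in the unshifted north
  south <- rep(c(FALSE, TRUE), each = 50)      # last 5 rows, row-major
  layers <- st$layers
  layers$BIO16 <- st$layers$BIO16 - 100 * south
  dry <- env_stack(st$grid, layers, scenario = "synthetic-dry")
  occ_n <- data.frame(cell = maxsuit:::cell_index(
    st$grid, rep(2500, 3), c(9500, 8500, 7500)))  # northern rows
  ss3 <- variable_shift_summary(st, dry, occ_n)
  expect_equal(ss3[ss3$variable == "BIO16" & ss3$domain == "occurrences", "q50"], 0)
  expect_lt(ss3[ss3$variable == "BIO16" & ss3$domain == "area", "q50"], 0)
})
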