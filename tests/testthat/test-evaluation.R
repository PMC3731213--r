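test_that("pearson_cc matches the covariance-formula oracle and validates input", {
  expect_equal(pearson_cc(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_cc(1:10, -(1:10)), -1)
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(15)
    expect_equal(pearson_cc(x, y), oracle_cc(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_cc(1:5, 1:4), "length")
  expect_error(pearson_cc(c(1, 2), c(3, 4)), "3")
  expect_error(pearson_cc(rep(1, 5), 1:5), "constant")
})

test_that("correlation p-values follow the t-transform", {
  expect_equal(cc_pvalue(0, 100, "two"), 1)
  expect_equal(cc_pvalue(1, 50), 0)
  # r = 0.15, n = 2000: one-tailed p below 1e-11
  expect_lt(cc_pvalue(0.15, 2000, "one"), 1e-11)
  # numeric-integration oracle of the t density, r = 0.5, n = 10
  r <- 0.5; n <- 10
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  dens <- function(t) {
    gamma((n - 1) / 2) / (sqrt((n - 2) * pi) * gamma((n - 2) / 2)) *
      (1 + t^2 / (n - 2))^(-(n - 1) / 2)
  }
  oracle <- integrate(dens, tstat, Inf, rel.tol = 1e-12)$value
  expect_equal(cc_pvalue(r, n, "one"), oracle, tolerance = 1e-9)
  expect_equal(cc_pvalue(r, n, "two"), 2 * oracle, tolerance = 1e-9)
})

test_that("modified Z-score matches hand arithmetic and is antisymmetric", {
  pool <- c(1, 2, 3, 4, 100)
  expect_equal(modified_zscore(100, pool), 0.6745 * 97 / 1, tolerance = 1e-12)
  expect_equal(modified_zscore(median(pool), pool), 0)
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(modified_zscore(2, sym), -modified_zscore(-2, sym))
  # MAD = 0 falls back to the mean-absolute-deviation denominator
  tied <- c(1, 1, 1, 1, 9)
  expect_equal(modified_zscore(9, tied), 8 / (1.253 * mean(abs(tied - 1))))
  expect_error(modified_zscore(1, rep(2, 5)), "dispersion")
  expect_error(modified_zscore(1, c(1, 2)), "pool")
})

test_that("rank AUC equals brute-force pairwise comparison", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3)), 1)
  expect_equal(roc_auc(rep(5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(9)
  for (i in 1:10) {
    sc <- sample(1:8, 20, replace = TRUE)  # with ties
    pos <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (length(unique(pos)) < 2) next
    expect_equal(roc_auc(sc, pos), oracle_auc(sc, pos))
  }
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "classes")
})

test_that("accessibility filtering zeroes inaccessible windows and helps gated data", {
  x <- c(1, 2, 3)
  expect_equal(accessibility_filtered_scores(x, c(TRUE, TRUE, TRUE)), x)
  expect_equal(accessibility_filtered_scores(x, rep(FALSE, 3)), c(0, 0, 0))
  expect_error(accessibility_filtered_scores(x, TRUE), "length")
  # planted gate: occupancy expressed only in accessible windows
  set.seed(21)
  occ <- runif(300, 0, 2)
  gate <- runif(300) < 0.4
  chip <- occ * gate + rnorm(300, 0, 0.1)
  expect_gt(pearson_cc(accessibility_filtered_scores(occ, gate), chip),
            pearson_cc(occ, chip))
})

test_that("semi-partial correlation equals the residual-regression oracle", {
  set.seed(13)
  # independence: SPCC reduces to the plain correlation
  x <- rnorm(200)
  y <- x + rnorm(200)
  z <- rnorm(200)  # independent of both
  sp <- semi_partial_cc(x, y, z)
  expect_equal(sp, pearson_cc(x, y), tolerance = 0.15)
  for (i in 1:25) {
    x <- rnorm(50); z <- rnorm(50)
    y <- 0.5 * x + 0.7 * z + rnorm(50)
    expect_equal(semi_partial_cc(x, y, z), oracle_spcc(x, y, z),
                 tolerance = 1e-10)
  }
  y2 <- rnorm(50)
  expect_error(semi_partial_cc(rnorm(50), y2, y2), "collinear")
})

test_that("overall CC is not a weighted mean of subset CCs", {
  # constructed separation: within each label the association is negative,
  # across labels strongly positive
  chip <- c(1:20, 101:120)
  pred <- c(20:1, 220:201) / 10
  labels <- rep(c("nonpeak", "peak"), each = 20)
  cc <- subset_cc(pred, chip, labels)
  expect_lt(cc[["peak"]], 0)
  expect_lt(cc[["nonpeak"]], 0)
  expect_gt(cc[["overall"]], 0.9)
  w <- 0.5
  expect_gt(abs(cc[["overall"]] - (w * cc[["peak"]] + w * cc[["nonpeak"]])),
            0.5)
})

test_that("trained gamma ratios track planted concentration changes", {
  # quadrant arithmetic
  fa <- list(fold_params = data.frame(log10_gamma1 = rep(2, 4)))
  fb <- list(fold_params = data.frame(log10_gamma1 = rep(1, 4)))
  g <- gamma_expression_consistency(fa, fb, 20, 10)
  expect_true(g$consistent)   # first quadrant
  g2 <- gamma_expression_consistency(fb, fa, 10, 20)
  expect_true(g2$consistent)  # third quadrant
  g3 <- gamma_expression_consistency(fa, fb, 5, 50)
  expect_false(g3$consistent)
  expect_error(gamma_expression_consistency(fa, fb, 0, 1), "positive")

  # planted concentration change: stage B at 10x the gamma of stage A
  p1 <- fix_primary()
  tma <- truth_model(p1, mode = "single", log10_gamma = c(1, 1))
  tmb <- truth_model(p1, mode = "single", log10_gamma = c(2, 2))
  dsa <- simulate_chip_dataset(tma, 60, 60, seed = 41)
  dsb <- simulate_chip_dataset(tmb, 60, 60, seed = 42)
  cfg <- stap_config("single", seed = 1)
  fita <- cross_validate_stap(dsa, list(p1), cfg)
  fitb <- cross_validate_stap(dsb, list(p1), cfg)
  out <- gamma_expression_consistency(fitb, fita, expr_a = 20, expr_b = 10)
  expect_gt(out$log_gamma_ratio, 0)
  expect_true(out$consistent)
})

test_that("a secondary identical to the primary adds no information", {
  # on single-motif truth data a duplicate of the primary is redundant
  p1 <- fix_primary()
  tm <- truth_model(p1, mode = "single")
  ds <- simulate_chip_dataset(tm, 100, 100, seed = 61)
  r <- assess_secondary_influence(ds, p1, pwm(p1$probs, name = "prim_copy"),
                                  mode = "cooperative", d_T = 150,
                                  n_shuffles = 0)
  expect_lt(abs(r$delta_cc), 0.04)
  expect_false(r$significant)
})

test_that("empirical p-values count ties as successes at 1/n resolution", {
  ds <- fix_coop_dataset()
  p1 <- fix_primary()
  p2 <- fix_secondary()
  r <- assess_secondary_influence(ds, p1, p2, "cooperative", 150,
                                  n_shuffles = 10, seed = 3,
                                  delta_cc_pool = c(r_dec <- rnorm(8, 0, 0.005),
                                                    0.08))
  expect_true(r$delta_cc >= 0.04)
  expect_true(r$pvalue %in% seq(0, 1, by = 0.1))
  expect_true(is.finite(r$zscore))
})
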