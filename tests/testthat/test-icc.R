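test_that("two-way ANOVA matches the brute-force definition sums", {
  set.seed(7)
  for (dims in list(c(3, 3), c(5, 4), c(12, 7))) {
    x <- matrix(rnorm(prod(dims), sd = 3), dims[1], dims[2])
    an <- two_way_anova(x)
    or <- anova_oracle(x)
    expect_equal(an$ss_rows, or$ss_rows, tolerance = 1e-10)
    expect_equal(an$ss_cols, or$ss_cols, tolerance = 1e-10)
    expect_equal(an$ss_error, or$ss_error, tolerance = 1e-8)
    expect_equal(an$ss_total, or$ss_total, tolerance = 1e-10)
  }
})

test_that("two-way ANOVA agrees with stats::aov on a small grid", {
  set.seed(12)
  x <- matrix(rnorm(6 * 5, 10, 2), 6, 5)
  an <- two_way_anova(x)
  d <- data.frame(y = as.vector(x),
                  row = factor(rep(seq_len(6), times = 5)),
                  col = factor(rep(seq_len(5), each = 6)))
  tab <- summary(stats::aov(y ~ row + col, data = d))[[1]]
  expect_equal(an$ss_rows, tab["row", "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$ss_cols, tab["col", "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$ss_error, tab["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$f_rows, tab["row", "F value"], tolerance = 1e-8)
  expect_equal(an$p_rows, tab["row", "Pr(>F)"], tolerance = 1e-8)
})

test_that("SS are additive and non-negative on random matrices", {
  set.seed(41)
  for (i in 1:25) {
    x <- matrix(rnorm(8 * 6, sd = runif(1, 0.1, 10)), 8, 6)
    an <- two_way_anova(x)
    expect_gte(an$ss_rows, 0); expect_gte(an$ss_cols, 0)
    expect_gte(an$ss_error, 0)
    expect_equal(an$ss_rows + an$ss_cols + an$ss_error, an$ss_total,
                 tolerance = 1e-9)
  }
})

test_that("constant matrices are flagged degenerate, not an F value", {
  an <- two_way_anova(matrix(5, 4, 4))
  expect_true(an$degenerate)
  expect_true(is.na(an$f_rows))
  est <- icc_from_anova(an)
  expect_true(est$degenerate)
  expect_true(is.na(est$icc))
})

test_that("missing cells and undersized grids are rejected", {
  x <- matrix(rnorm(9), 3, 3); x[2, 2] <- NA
  expect_error(two_way_anova(x), "complete")
  expect_error(two_way_anova(matrix(1:3, 3, 1)), "at least 2")
})

test_that("ICC equals Cronbach's alpha on 100 random matrices", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(4:12, 1); k <- sample(3:8, 1)
    x <- matrix(rnorm(n * k), n, k) +
      rnorm(n) %o% rep(1, k) * runif(1, 0, 2)
    est <- icc_from_anova(two_way_anova(x))
    expect_equal(est$icc, alpha_oracle(x), tolerance = 1e-9)
  }
})

test_that("ICC is invariant under row and column permutations", {
  set.seed(5)
  x <- matrix(rnorm(10 * 6), 10, 6) + rnorm(10)
  e0 <- icc_from_anova(two_way_anova(x))
  e1 <- icc_from_anova(two_way_anova(x[sample(10), ]))
  e2 <- icc_from_anova(two_way_anova(x[, sample(6)]))
  expect_equal(e1$icc, e0$icc, tolerance = 1e-12)
  expect_equal(e2$icc, e0$icc, tolerance = 1e-12)
})

test_that("published ANOVA margins reproduce ICC and F to print precision", {
  hi <- icc_from_anova(anova_from_ss(3044.90, 420L, 7643.33, 4620L,
                                     ss_cols = 3915.00, df_cols = 11L))
  expect_equal(round(hi$icc, 3), 0.772)
  expect_equal(round(hi$f_obs, 2), 4.38)
  expect_lt(hi$p, 0.001)

  lo <- icc_from_anova(anova_from_ss(1488.20, 420L, 9573.44, 4620L,
                                     ss_cols = 503.22, df_cols = 11L))
  expect_equal(round(lo$icc, 3), 0.415)
  expect_equal(round(lo$f_obs, 2), 1.71)

  ideal <- anova_from_ss(430.96, 420L, 4549.82, 4620L,
                         ss_cols = 17.964, df_cols = 11L)
  expect_equal(round(ideal$f_rows, 2), 1.04)
  expect_equal(round(ideal$p_rows, 3), 0.276, tolerance = 0.01)
})

test_that("the F-based CI pins the average-measure consistency flavor", {
  ci1 <- icc_confidence_interval(0.040, n = 421, k = 13)
  expect_equal(unname(ci1), c(-0.101, 0.170), tolerance = 0.005)
  ci2 <- icc_confidence_interval(0.533, n = 421, k = 13)
  expect_equal(unname(ci2), c(0.464, 0.594), tolerance = 0.005)
  # interval brackets the point estimate
  est <- icc_from_anova(two_way_anova(matrix(rnorm(60), 10, 6)))
  expect_lte(est$ci_low, est$icc)
  expect_gte(est$ci_high, est$icc)
  # alpha -> 1: the interval degenerates to a single point at the
  # estimate (up to the median-F bias of the pivot)
  wide <- icc_confidence_interval(0.5, alpha = 0.999999, n = 20, k = 5)
  expect_lt(wide[["high"]] - wide[["low"]], 1e-4)
  expect_equal(unname(wide[["low"]]), 0.5, tolerance = 0.05)
})

test_that("SEM follows SD * sqrt(1 - reliability)", {
  expect_equal(sem(10, 0.75), 5)
  expect_equal(sem(3, 1), 0)
  expect_equal(sem(3, 0), 3)
  expect_error(sem(3, 1.2), "exceed")
  expect_error(sem(-1, 0.5), "non-negative")
})

test_that("separation and strata indices follow their closed forms", {
  s <- strata_index(0.5)
  expect_equal(s$g_p, 1)
  expect_equal(round(s$strata, 2), 1.67)
  expect_equal(strata_index(0)$g_p, 0)
  expect_equal(strata_index(0)$strata, 1 / 3)
  expect_equal(strata_index(0.8)$g_p, 2)
  expect_equal(strata_index(0.8)$strata, 3)
  expect_error(strata_index(1), "\\[0, 1\\)")
})

test_that("yearly ICC series maps blocks to estimates and rejects burn-in", {
  em <- generate_expenditure_series(30, 36, noise_cv = 0.1, seed = 8)
  sc <- sequential_scan(em)
  blocks <- yearly_blocks(colnames(em), 13L)
  yearly <- yearly_icc_series(sc, blocks)
  expect_named(yearly, c("2000", "2001"))
  expect_s3_class(yearly[["2000"]], "icc_estimate")
  der <- attr(yearly[["2000"]], "derived")
  expect_true(all(c("sem", "g_p", "strata") %in% names(der)))

  # permuting hospitals leaves every estimate unchanged
  perm <- sample(nrow(em))
  scp <- sequential_scan(expenditure_matrix(unclass(em)[perm, ]))
  yp <- yearly_icc_series(scp, blocks)
  expect_equal(yp[["2001"]]$icc, yearly[["2001"]]$icc, tolerance = 1e-12)

  bad <- xmricc:::new_xmr_scores(cbind(NA_real_ * sc$sd[, 1:2], sc$sd),
                                 cbind(NA_integer_ * sc$bands[, 1:2],
                                       sc$bands),
                                 "ten_band", 12L)
  expect_error(yearly_icc_series(bad, list(structure(
    list(year = 1999L, columns = 1:12), class = "year_block"))),
    "1999")
})

test_that("trend statistics reproduce the closed-form t and r-squared", {
  # synthesize a 10-year series with correlation exactly -0.94 by
  # orthogonal construction
  years <- 2000:2009
  z1 <- scale(years)[, 1]
  resid <- stats::resid(lm(rnorm(10) ~ z1))
  z2 <- resid / sqrt(sum(resid^2) / 9)
  icc <- 0.6 + 0.1 * (-0.94 * z1 + sqrt(1 - 0.94^2) * z2)
  names(icc) <- years
  tr <- trend_stats(icc)
  expect_equal(tr$r, -0.94, tolerance = 1e-10)
  expect_equal(round(tr$t_stat, 2), 7.79)
  expect_equal(round(tr$r_squared, 2), 0.88)
  expect_lt(tr$p, 0.0001)
  expect_lt(tr$slope, 0)

  flat <- setNames(rep(0.5, 5), 2001:2005)
  expect_true(is.na(trend_stats(flat)$r))
  expect_error(trend_stats(setNames(c(.1, .2), 2001:2002)), "at least 3")
})

test_that("Pearson chi-square matches the definition and scales linearly", {
  even <- chisq_table(matrix(10, 2, 2))
  expect_equal(even$chi2, 0)
  skew <- chisq_table(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(skew$chi2, 4 * 25 / 15, tolerance = 1e-3)
  expect_equal(skew$df, 1L)
  dbl <- chisq_table(2 * matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(dbl$chi2, 2 * skew$chi2, tolerance = 1e-9)
  expect_error(chisq_table(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
})
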