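# Statistics module: paired tests, regression, CV, percent reductions,
# and the cohort comparison report.

test_that("the signed-rank test matches brute-force enumeration on a small sample", {
  x <- c(2, 4, 6, 8, 10, 12); y <- c(1, 2, 3, 4, 5, 6)  # differences 1..6
  # independent oracle: enumerate all 2^6 sign assignments of ranks 1..6
  W_obs <- sum(rank(abs(x - y)))
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  W_all <- as.matrix(signs) %*% rank(abs(x - y))
  p_exact <- min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
  expect_equal(p_exact, 0.03125)
  res <- paired_wilcoxon(x, y)
  expect_equal(res$p.value, p_exact)
  expect_equal(res$statistic, 21)
})

test_that("the signed-rank test is degenerate-safe and sign-symmetric", {
  expect_warning(res <- paired_wilcoxon(1:5, 1:5), "zero")
  expect_equal(res$p.value, 1)
  x <- c(3.2, 1.1, 4.8, 2.2, 9.9, 5.5, 7.1)
  y <- c(1.0, 2.3, 3.3, 6.1, 4.4, 5.0, 7.4)
  expect_equal(paired_wilcoxon(x, y)$p.value, paired_wilcoxon(y, x)$p.value)
})

test_that("exact signed-rank p-values agree with the reference implementation when ties are absent", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(paired_wilcoxon(x, y)$p.value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large n: continuity-corrected normal approximation
  set.seed(9)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  expect_equal(paired_wilcoxon(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-9)
  # ties still yield a valid exact p-value
  res <- paired_wilcoxon(c(5, 5, 7, 9, 9, 1), c(4, 4, 5, 6, 6, 2))
  expect_true(res$p.value > 0 && res$p.value <= 1)
})

test_that("the paired t-test matches the textbook statistic and handles degeneracy", {
  x <- c(5.1, 6.2, 4.8, 7.0, 5.9); y <- c(4.3, 5.1, 5.2, 6.1, 5.0)
  d <- x - y
  res <- paired_ttest(x, y)
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$p.value, t.test(x, y, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_warning(r0 <- paired_ttest(1:4, 1:4), "identical")
  expect_equal(r0$statistic, 0); expect_equal(r0$p.value, 1)
  r1 <- paired_ttest(c(1, 3, 1, 3), c(2, 2, 2, 2))  # differences 1,-1 each
  expect_equal(r1$statistic, 0); expect_equal(r1$p.value, 1)
  expect_warning(r2 <- paired_ttest(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_equal(r2$p.value, 0)
})

test_that("regression recovers exact fits and decays for shuffled data", {
  x <- c(1, 2, 3, 5, 8)
  f <- fit_regression(x, 2 * x)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  set.seed(4)
  xs <- rlnorm(1000)
  expect_lt(fit_regression(xs, sample(xs))$r2, 0.05)
  expect_equal(fit_regression(xs, 3 * xs + 1)$r2,
               fit_regression(xs * 10, 3 * xs + 1)$r2, tolerance = 1e-12)
  expect_error(fit_regression(rep(1, 5), 1:5), "zero variance")
})

test_that("the coefficient of variation is the sample sd over the mean", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  v <- c(0.8, 1.9, 4.4)
  expect_equal(coefficient_of_variation(3 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(2), "2 values")
})

test_that("percent reductions round half away from zero to whole percents", {
  expect_identical(percent_reduction(102, 66), 35L)
  expect_identical(percent_reduction(61, 43), 30L)
  expect_identical(percent_reduction(40, 23), 43L)
  expect_identical(percent_reduction(7, 7), 0L)
  expect_identical(percent_reduction(200, 199), 1L)   # 0.5 rounds up
  expect_identical(percent_reduction(100, 102), -2L)
  expect_error(percent_reduction(0, 5), "mean_ref")
})

test_that("the cohort report is internally consistent and degenerates cleanly", {
  segs <- generate_cohort(3, small_config("apical", 2),
                          small_config("basal", 2), seed = 31, render = FALSE)
  an <- suppressWarnings(analyze_cohort(segs, from = "truth"))
  rep <- suppressWarnings(compare_bf_ef(an))
  s <- an$segments
  ok <- !is.na(s$ratio_bf) & !is.na(s$ratio_ef) & !is.na(s$kh)
  expect_equal(rep$ratios$mean_bf, mean(s$ratio_bf[ok]), tolerance = 1e-12)
  expect_equal(rep$ratios$mean_ef, mean(s$ratio_ef[ok]), tolerance = 1e-12)
  expect_equal(rep$ratios$difference,
               mean(s$ratio_ef[ok]) - mean(s$ratio_bf[ok]), tolerance = 1e-12)
  expect_equal(rep$ratios$cv_ef, coefficient_of_variation(s$ratio_ef[ok]),
               tolerance = 1e-12)
  pooled_d <- rep$parameters[rep$parameters$group == "pooled" &
                               rep$parameters$parameter == "D", ]
  expect_equal(pooled_d$mean_bf, mean(s$mean_d_bf[!is.na(s$mean_d_bf) &
                                                    !is.na(s$mean_d_ef)]),
               tolerance = 1e-12)
  # identical BF and EF calls collapse every contrast to zero
  s2 <- s
  for (col in c("kht", "khs", "khts", "mean_d", "n_px", "n_mx", "n_total",
                "ratio"))
    s2[[paste0(col, "_ef")]] <- s2[[paste0(col, "_bf")]]
  rep2 <- suppressWarnings(compare_bf_ef(s2))
  expect_true(all(rep2$counts$pct_reduction == 0L))
  expect_equal(rep2$ratios$difference, 0)
  expect_output(print(rep2), "Kh/Kht ratio")
})
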