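test_that("signed-rank handles degenerate and textbook cases", {
  r <- wilcoxon_signed_rank(c(3, 5, 7, 9), c(3, 5, 7, 9))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$flag, "degenerate")

  # all-positive differences {1..5}: V = 15, exact two-sided p = 2/32
  r5 <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5))
  expect_equal(r5$statistic, 15)
  expect_equal(r5$p_value, 2 / 32)
  expect_equal(r5$p_value, bf_signed_rank_p(c(1, 2, 3, 4, 5), rep(0, 5)))
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
  expect_error(wilcoxon_signed_rank(1:2, 2:3), "3 pairs")
})

test_that("exact signed-rank equals enumeration and wilcox.test where defined", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    a <- round(rnorm(n, sd = 4), if (i %% 2) 1 else 0)  # even i: many ties
    b <- round(rnorm(n, sd = 4), if (i %% 2) 1 else 0)
    if (all(a == b)) next
    p <- wilcoxon_signed_rank(a, b)$p_value
    expect_equal(p, bf_signed_rank_p(a, b), info = paste("case", i))
    d <- a - b
    if (!any(d == 0) && !anyDuplicated(abs(d)))
      expect_equal(p, wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("rank-sum handles ties, textbook cases and separation", {
  expect_equal(rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # {1,2} vs {3,4}: complete separation, W = 3, p = 2 * 1/C(4,2)
  r <- rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$p_value, bf_rank_sum_p(c(1, 2), c(3, 4)))
  expect_error(rank_sum(1, c(2, 3)), "at least 2")
})

test_that("exact rank-sum equals enumeration and wilcox.test where defined", {
  set.seed(202)
  for (i in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- round(rnorm(na, sd = 3), if (i %% 2) 1 else 0)
    b <- round(rnorm(nb, sd = 3), if (i %% 2) 1 else 0)
    p <- rank_sum(a, b)$p_value
    expect_equal(p, bf_rank_sum_p(a, b), info = paste("case", i))
    if (!anyDuplicated(c(a, b)))
      expect_equal(p, wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("approximate modes agree with the normal-theory references", {
  set.seed(303)
  a <- rnorm(25); b <- rnorm(25)
  p_pkg <- wilcoxon_signed_rank(a, b)$p_value
  p_ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE,
                       correct = FALSE)$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  p_rs <- rank_sum(a, b)$p_value
  p_rs_ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(p_rs, p_rs_ref, tolerance = 1e-10)
})

test_that("Kruskal-Wallis matches the hand rank formula", {
  # {1,2},{3,4},{5,6}: ranks 1..6, H = 12/(6*7) * sum(R_j^2/2) - 3*7 = 32/7
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(r$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(r$p_value, pchisq(32 / 7, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  d <- kruskal_wallis(list(c(5, 5), c(5, 5)))
  expect_equal(d$statistic, 0)
  expect_equal(d$p_value, 1)
  expect_equal(d$flag, "degenerate")
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("Bonferroni adjustment caps, never decreases, honours m", {
  expect_equal(bonferroni_adjust(0.02, m = 1), 0.02)
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  set.seed(11)
  p <- runif(6)
  expect_true(all(bonferroni_adjust(p, m = 8) >= p))
  expect_true(all(bonferroni_adjust(p, m = 8) <= 1))
  expect_error(bonferroni_adjust(p, m = 2), "family size")
})

test_that("coefficient of variation is correct and scale-invariant", {
  expect_equal(cov_percent(c(5, 5, 5)), 0)
  expect_equal(cov_percent(c(90, 100, 110)), 10)
  v <- c(88, 95, 103, 110)
  expect_equal(cov_percent(v * 7.3), cov_percent(v))
  expect_error(cov_percent(c(-1, 1)), "zero mean")
  expect_error(cov_percent(5), "2 values")
})

test_that("linear fits match hand-computed normal equations", {
  f <- linear_fit_r2(c(0, 1, 2), c(0, 1, 3))
  expect_equal(f$slope, 1.5, tolerance = 1e-12)
  expect_equal(f$intercept, -1 / 6, tolerance = 1e-12)
  expect_equal(f$r_squared, 27 / 28, tolerance = 1e-12)
  expect_equal(f$p_value, 2 * pt(-sqrt(27 / 28 / (1 / 28)), df = 1),
               tolerance = 1e-9)

  col <- linear_fit_r2(1:5, 3 + 2 * (1:5))
  expect_equal(col$r_squared, 1)
  expect_lt(col$p_value, 1e-10)

  # a ~2x calibration offset leaves the correlation intact (scale-free R^2)
  set.seed(5)
  mri <- c(78, 45, 84, 41, 90, 50)
  assay <- mri / 2 + rnorm(6, sd = 1)
  expect_gt(linear_fit_r2(mri, assay)$r_squared, 0.9)

  expect_error(linear_fit_r2(rep(2, 4), 1:4), "constant")
  flat <- linear_fit_r2(1:4, rep(3, 4))
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)
})
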