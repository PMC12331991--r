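# Statistical primitives against closed-form and exhaustive-enumeration
# oracles.

test_that("SMA regression matches closed-form arithmetic", {
  # exact line
  f <- model2_regression(c(0, 1, 2), c(1, 2, 3))
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  # closed-form oracle: slope = sign(r) sd(y)/sd(x), through the centroid
  x <- c(0, 1, 2); y <- c(0, 1, 4)
  f <- model2_regression(x, y)
  expect_equal(f$slope, sd(y) / sd(x))
  expect_equal(f$slope, 2.081666, tolerance = 1e-6)
  expect_equal(f$intercept, mean(y) - sd(y) / sd(x) * mean(x))
  expect_equal(f$intercept, -0.4149993, tolerance = 1e-6)

  # axis-exchange symmetry: slope exactly reciprocal
  b <- model2_regression(y, x)
  expect_equal(b$slope, 1 / f$slope)

  # errors
  expect_error(model2_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(model2_regression(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("SMA slope is the geometric mean of the two OLS slopes", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(40); y <- 0.8 * x + rnorm(40, 0, 0.7)
    sma <- model2_regression(x, y)$slope
    b_yx <- ols_regression(x, y)$slope
    b_xy <- ols_regression(y, x)$slope
    # |sma| = geometric mean of b(y~x) and 1/b(x~y)
    expect_equal(abs(sma), sqrt(b_yx / b_xy), tolerance = 1e-10)
  }
})

test_that("OLS contract: exact line, null slope, duplication invariance", {
  f <- ols_regression(c(1, 2, 3, 4), c(3, 5, 7, 9))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)

  set.seed(5)
  x <- rnorm(4000); y <- rnorm(4000)
  expect_lt(abs(ols_regression(x, y)$slope), 0.06)  # ~2 SE at n = 4000

  x <- c(0, 1, 3, 7); y <- c(2, 2.5, 4, 9)
  f1 <- ols_regression(x, y)
  f2 <- ols_regression(rep(x, 2), rep(y, 2))
  expect_equal(f1$slope, f2$slope)
  expect_equal(f1$intercept, f2$intercept)
})

test_that("Welch t matches the hand formula and degenerates sensibly", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  w <- welch_t(a, b)
  # direct Welch-Satterthwaite arithmetic
  se2 <- var(a) / 3 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(w$t, t_hand)
  expect_equal(w$df, df_hand)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  # equal variances and ns: Welch t equals Student t numerically
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20) + 0.5
  expect_equal(welch_t(x, y)$t,
               unname(t.test(x, y, var.equal = TRUE)$statistic),
               tolerance = 0.02)
  expect_error(welch_t(c(1), c(1, 2)), "n >= 2")
})

test_that("Wilcoxon rank-sum: exact enumeration oracle and invariances", {
  # a = {1,2}, b = {3,4}: 6 equally likely orderings, the observed split is
  # one of the two extremes -> two-sided exact p = 2/6 = 1/3
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$W, 0)
  expect_equal(w$p_value, 1 / 3)

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  w1 <- wilcoxon_rank_sum(c(1, 5, 9), c(2, 3, 4))
  w2 <- wilcoxon_rank_sum(c(1, 5, 9) + 100, c(2, 3, 4) + 100)
  expect_equal(w1$W, w2$W)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("bootstrap matches the exhaustive 27-resample oracle for n = 3", {
  # enumerate all 3^3 ordered resamples of {1,2,9} and their medians
  vals <- c(1, 2, 9)
  grid <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
  meds <- apply(grid, 1L, function(r) median(vals[unlist(r)]))
  expect_equal(as.numeric(table(meds)) / 27, c(7, 13, 7) / 27)
  med_exact <- median(meds)            # 2
  sd_exact <- sqrt(mean(meds^2) - mean(meds)^2)  # population SD over resamples
  expect_equal(med_exact, 2)
  expect_equal(sd_exact, 3.2470, tolerance = 1e-4)

  b <- bootstrap_stat(vals, median, n_sim = 50000, seed = 9)
  expect_equal(b$median, med_exact)
  expect_equal(b$se, sd_exact, tolerance = 0.05)
  expect_equal(b$ci_low, 1)
  expect_equal(b$ci_high, 9)
})

test_that("bootstrap degenerate and contract cases", {
  b <- bootstrap_stat(rep(4, 10), median, n_sim = 500, seed = 1)
  expect_equal(b$median, 4)
  expect_equal(b$se, 0)
  expect_equal(c(b$ci_low, b$ci_high), c(4, 4))
  expect_warning(bootstrap_stat(c(1, 2, 3), median, n_sim = 50, seed = 1),
                 "unstable")
  expect_error(bootstrap_stat(c(1, 2, 3), median, n_sim = 500), "seed")
  # same seed, same data -> identical
  set.seed(123); v <- rnorm(15)
  expect_identical(bootstrap_stat(v, median, n_sim = 2000, seed = 5),
                   bootstrap_stat(v, median, n_sim = 2000, seed = 5))
})

test_that("bootstrap percentile CI coverage for the median is ~95%", {
  # scaled down from the stated 1000 repetitions to fit the test budget:
  # 400 Gaussian samples of n = 30, 800 resamples each
  set.seed(2024)
  seeds <- sample.int(1e6, 400)
  cover <- vapply(seeds, function(s) {
    v <- rnorm(30)
    b <- bootstrap_stat(v, median, n_sim = 800, seed = s)
    b$ci_low <= 0 && 0 <= b$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("PERMANOVA reproduces the exhaustive 1-D toy exactly", {
  vals <- c(0, 0, 1, 3)
  groups <- c("a", "a", "b", "b")
  res <- permanova(matrix(vals, ncol = 1), groups, n_perm = 9999, seed = 4)
  expect_equal(res$ss_total, 6)
  expect_equal(res$ss_within, 2)
  expect_equal(res$F, 4)
  expect_equal(res$r_squared, 2 / 3)
  # exact enumeration: 6 splits, F >= 4 for 2 of them -> p = 1/3
  enum <- permanova_enumerate(vals, c(2, 2))
  expect_equal(mean(enum$f_all >= 4 - 1e-12), 1 / 3)
  expect_equal(res$p_value, 1 / 3, tolerance = 0.03)
})

test_that("PERMANOVA matches vegan::adonis2 on multivariate data", {
  set.seed(8)
  x <- matrix(rnorm(12 * 4), nrow = 12)
  g <- rep(c("m", "s"), each = 6)
  x[g == "s", 1] <- x[g == "s", 1] + 1.5
  mine <- permanova(x, g, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(dist(x) ~ g, permutations = 999)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 0.05)
})

test_that("PERMANOVA trivial and error cases", {
  x <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 1)
  res <- permanova(x, rep(c("a", "b"), each = 3), n_perm = 199, seed = 1)
  expect_lt(res$F, 1e-9)
  expect_gt(res$p_value, 0.9)
  expect_error(permanova(x, c("a", rep("b", 5)), n_perm = 99, seed = 1),
               ">= 2 samples per group")
  expect_error(permanova(x, rep("a", 6), n_perm = 99, seed = 1), ">= 2 groups")
})
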