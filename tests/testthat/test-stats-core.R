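test_that("RMA regression is exact on collinear data and symmetric under axis interchange", {
  fit <- rma_regression(c(1, 2, 3, 4), c(3, 5, 7, 9), n_boot = 0)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$n, 4L)

  inv <- rma_regression(c(3, 5, 7, 9), c(1, 2, 3, 4), n_boot = 0)
  expect_equal(inv$slope, 0.5)

  # for exactly collinear data RMA, MA (eigen) and OLS slopes coincide
  x <- seq(-2, 5, length.out = 9)
  y <- -1.7 * x + 0.4
  fit <- rma_regression(x, y, n_boot = 0)
  ols <- rma_regression(x, y, n_boot = 0,
                        method = "ordinary_least_squares")
  expect_equal(fit$slope, -1.7, tolerance = 1e-12)
  expect_equal(ols$slope, -1.7, tolerance = 1e-12)
  expect_equal(rma_oracle(x, y), -1.7, tolerance = 1e-10)
})

test_that("RMA slope matches the independent eigen-decomposition oracle on random data", {
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 20))
    y <- runif(1, -3, 3) * x + rnorm(n, sd = runif(1, 0.1, 5))
    fit <- rma_regression(x, y, n_boot = 0)
    expect_equal(fit$slope, rma_oracle(x, y), tolerance = 1e-8)
  }
})

test_that("RMA slope is exactly scale-equivariant in y", {
  set.seed(7)
  x <- rnorm(12)
  y <- 0.5 * x + rnorm(12, sd = 0.3)
  base <- rma_regression(x, y, n_boot = 0)$slope
  for (c_fac in c(-3, 0.01, 7, 1e4)) {
    expect_equal(rma_regression(x, c_fac * y, n_boot = 0)$slope,
                 c_fac * base, tolerance = 1e-12)
  }
})

test_that("RMA regression validates its inputs", {
  expect_error(rma_regression(1:4, 1:3), "same length")
  expect_error(rma_regression(1:2, 2:3), "at least 3")
  expect_error(rma_regression(c(1, 1, 1), 1:3), "zero range")
  expect_error(rma_regression(1:3, c(2, 2, 2)), "zero range")
})

test_that("parametric and permutation p-values agree on strong and null signals", {
  set.seed(11)
  x <- rnorm(30)
  y_strong <- 2 * x + rnorm(30, sd = 0.1)
  p_param <- rma_regression(x, y_strong, n_boot = 0)$p_value
  p_perm <- rma_regression(x, y_strong, n_boot = 0,
                           n_permutations = 499, seed = 1)$p_value
  expect_lt(p_param, 1e-6)
  expect_equal(p_perm, 1 / 500)  # smallest attainable permutation p

  y_null <- rnorm(30)
  p_param0 <- rma_regression(x, y_null, n_boot = 0)$p_value
  p_perm0 <- rma_regression(x, y_null, n_boot = 0,
                            n_permutations = 499, seed = 1)$p_value
  expect_gt(p_param0, 0.01)
  expect_gt(p_perm0, 0.01)
})

test_that("bootstrap slope interval brackets the estimate and covers the true slope", {
  set.seed(3)
  x <- rnorm(40)
  y <- 0.05 * x + rnorm(40, sd = 0.02)
  fit <- rma_regression(x, y, n_boot = 499, seed = 5)
  expect_lte(fit$slope_ci_low, fit$slope)
  expect_gte(fit$slope_ci_high, fit$slope)
  # seeded bootstrap is reproducible
  fit2 <- rma_regression(x, y, n_boot = 499, seed = 5)
  expect_identical(fit$slope_ci_low, fit2$slope_ci_low)

  # empirical coverage on simulated linear data at nominal 95%; the
  # estimator is symmetric in x and y, so the noise is too (10% relative
  # on each axis)
  set.seed(2024)
  cover <- vapply(1:100, function(i) {
    xt <- rnorm(200)
    xx <- xt + rnorm(200, sd = 0.1)
    yy <- 0.05 * xt + rnorm(200, sd = 0.005)
    f <- rma_regression(xx, yy, n_boot = 499, seed = i)
    f$slope_ci_low <= 0.05 && f$slope_ci_high >= 0.05
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("tanh light-response fit recovers generating parameters and limit behaviour", {
  par <- seq(0, 2000, by = 40)
  yield <- tanh_response(par, a = 0.6, b = 0.004)
  fit <- fit_tanh_response(par, yield)
  expect_equal(fit$a, 0.6, tolerance = 1e-6)
  expect_equal(fit$b, 0.004, tolerance = 1e-6)
  expect_true(fit$converged)

  # tanh(0) = 0 and the plateau is approached from below
  expect_equal(tanh_response(0, fit$a, fit$b), 0)
  expect_lt(tanh_response(1000, fit$a, fit$b), fit$a)
  expect_equal(tanh_response(1e7, fit$a, fit$b), fit$a, tolerance = 1e-9)

  # constant yield observed only at saturating PAR: the value is the plateau
  flat <- fit_tanh_response(c(800, 1000, 1200, 1500, 2000), rep(0.42, 5))
  expect_equal(flat$a, 0.42, tolerance = 1e-9)

  expect_error(fit_tanh_response(c(0, 1), c(0, 1)), "at least 5")
})

test_that("tanh fit is unbiased within Monte-Carlo error under 5% noise", {
  par <- seq(0, 2000, by = 50)
  true <- tanh_response(par, 0.6, 0.004)
  set.seed(99)
  est <- t(vapply(1:60, function(i) {
    f <- fit_tanh_response(par, true * (1 + rnorm(length(par), sd = 0.05)))
    c(f$a, f$b)
  }, numeric(2)))
  se_a <- sd(est[, 1]) / sqrt(nrow(est))
  se_b <- sd(est[, 2]) / sqrt(nrow(est))
  expect_lt(abs(mean(est[, 1]) - 0.6), 4 * se_a)
  expect_lt(abs(mean(est[, 2]) - 0.004), 4 * se_b)
})

test_that("one-way ANOVA with Tukey HSD matches textbook computation", {
  # identical groups: no variance between, nothing significant
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anova_tukey(same)
  expect_equal(res$f_statistic, 0)
  expect_false(any(res$table$significant))

  # two groups: F equals the squared pooled t statistic
  g2 <- list(x = c(1.1, 2.0, 1.4, 1.7), y = c(2.4, 3.1, 2.2, 2.9))
  res2 <- anova_tukey(g2)
  tt <- ttest_unpaired(g2$x, g2$y, var_equal = TRUE)
  expect_equal(res2$f_statistic, tt$statistic^2, tolerance = 1e-10)
  # ptukey is computed by numerical integration; agreement is to ~1e-5
  expect_equal(res2$table$p_adj, tt$p_value, tolerance = 1e-4)

  # 3 x 3 fixture against the sums-of-squares oracle
  g3 <- list(control = c(0.21, 0.19, 0.23),
             fe = c(0.45, 0.40, 0.43),
             n = c(0.22, 0.25, 0.20))
  res3 <- anova_tukey(g3)
  orc <- anova_oracle(g3)
  expect_equal(res3$f_statistic, orc$f, tolerance = 1e-10)
  expect_equal(res3$p_value, orc$p, tolerance = 1e-10)
  expect_true(res3$table$significant[res3$table$pair == "fe-control"])
  expect_false(res3$table$significant[res3$table$pair == "n-control"])

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), ">= 2 replicates")
})

test_that("unpaired t-test handles degenerate samples and matches the Welch formula", {
  expect_equal(ttest_unpaired(c(1, 1, 1), c(1, 1))$p_value, 1)
  expect_equal(ttest_unpaired(c(1, 1), c(2, 2))$p_value, 0)
  big <- ttest_unpaired(rnorm(20, 100, 0.1), rnorm(20, 0, 0.1))
  expect_lt(big$p_value, 1e-6)

  x <- c(3.1, 2.8, 3.6, 3.0, 2.5)
  y <- c(4.0, 4.4, 3.9, 5.1)
  res <- ttest_unpaired(x, y)
  orc <- welch_oracle(x, y)
  expect_equal(res$statistic, orc$t, tolerance = 1e-12)
  expect_equal(res$df, orc$df, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
})

test_that("time-based rolling mean respects the window and ignores gaps", {
  t_min <- c(0, 5, 10, 15, 20, 25, 30)
  expect_equal(rolling_mean(t_min, rep(2.5, 7), window = 17), rep(2.5, 7))
  expect_equal(rolling_mean(0, 4.2, window = 17), 4.2)

  # centred window leaves the interior of a linear ramp unchanged
  v <- 0.1 * t_min
  sm <- rolling_mean(t_min, v, window = 17)
  expect_equal(sm[3:5], v[3:5])

  # irregular cadence: the window is temporal, not a sample count
  t_irr <- c(0, 1, 2, 60, 61, 62)
  v_irr <- c(1, 1, 1, 5, 5, 5)
  sm_irr <- rolling_mean(t_irr, v_irr, window = 10)
  expect_equal(sm_irr, v_irr)  # the two clusters never mix

  # missing values are dropped from the window, not propagated
  sm_na <- rolling_mean(c(0, 5, 10), c(1, NA, 3), window = 30)
  expect_equal(sm_na, c(2, 2, 2))

  expect_error(rolling_mean(c(3, 1, 2), 1:3, 5), "non-decreasing")
})
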