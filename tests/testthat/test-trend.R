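test_that("genotype counts transform to log2 with domain checking", {
  expect_equal(log_genotypes(1L), 0)
  expect_equal(log_genotypes(4L), 2)
  expect_equal(log_genotypes(3L), log2(3))
  expect_error(log_genotypes(0L), ">= 1")
})

test_that("fixing delta at zero reduces GLS exactly to OLS", {
  set.seed(31)
  x <- rep(c(0, 1, 2, 3), each = 25)
  y <- 0.1 - 0.2 * x + rnorm(100, 0, 0.5)
  f <- fit_gls_varexp(x, y, delta = 0)
  o <- lm(y ~ x)
  expect_equal(unname(f$beta), unname(coef(o)), tolerance = 1e-8)
  expect_equal(f$t_slope, unname(summary(o)$coefficients[2, 3]),
               tolerance = 1e-8)
  expect_error(fit_gls_varexp(rep(1, 20), rnorm(20)), "constant predictor")
})

test_that("estimates agree with the reference GLS implementation", {
  set.seed(32)
  n <- 250
  x <- sample(c(0, 1, log2(3), 2, log2(6), 3), n, TRUE)
  mu <- 0.2 + 0.3 * x
  y <- mu + rnorm(n, 0, 0.6 * exp(0.3 * mu))
  f <- fit_gls_varexp(x, y)
  ref <- nlme::gls(y ~ x, weights = nlme::varExp(form = ~ fitted(.)),
                   method = "ML")
  expect_equal(unname(f$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(f$delta,
               unname(coef(ref$modelStruct$varStruct)), tolerance = 1e-4)
  expect_equal(f$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
  expect_equal(f$t_slope, unname(summary(ref)$tTable[2, 3]),
               tolerance = 1e-4)
})

test_that("rescaling the response rescales the fit and preserves the t statistic", {
  set.seed(33)
  x <- runif(120, 0, 3)
  y <- 0.3 + 0.25 * x + rnorm(120, 0, 0.4 * exp(0.2 * x))
  f1 <- fit_gls_varexp(x, y)
  f3 <- fit_gls_varexp(x, 3 * y)
  expect_equal(unname(f3$beta), 3 * unname(f1$beta), tolerance = 1e-6)
  expect_equal(f3$t_slope, f1$t_slope, tolerance = 1e-6)
})

test_that("the profile likelihood over delta is unimodal at the optimum", {
  set.seed(34)
  x <- runif(150, 0, 3)
  y <- 0.2 + 0.3 * x + rnorm(150, 0, 0.5 * exp(0.25 * (0.2 + 0.3 * x)))
  f <- fit_gls_varexp(x, y)
  X <- cbind(1, x)
  grid <- seq(f$delta - 2, f$delta + 2, length.out = 161)
  prof <- vapply(grid, function(d) {
    trophmeta:::.gls_profile(d, X, y, f$fitted)$ll
  }, numeric(1))
  # number of sign changes of the first difference is exactly one
  s <- sign(diff(prof))
  expect_equal(sum(diff(s[s != 0]) != 0), 1L)
})

test_that("the variance parameter is recovered in simulation", {
  # delta = 0.3, n = 500 per replicate
  deltas <- numeric(200)
  set.seed(35)
  for (i in 1:200) {
    x <- runif(500, 0, 3)
    mu <- 0.1 + 0.3 * x
    y <- mu + rnorm(500, 0, 0.5 * exp(0.3 * mu))
    deltas[i] <- fit_gls_varexp(x, y)$delta
  }
  expect_lt(abs(mean(deltas) - 0.3), 0.1)
})

test_that("confidence band is narrowest at the weighted predictor mean", {
  set.seed(36)
  x <- runif(200, 0, 3)
  y <- 0.2 + 0.4 * x + rnorm(200, 0, 0.4 * exp(0.3 * x))
  f <- fit_gls_varexp(x, y)
  xbar <- sum(f$weights * x) / sum(f$weights)
  grid <- sort(c(xbar, seq(min(x), max(x), length.out = 51)))
  b <- predict_with_band(f, grid)
  hw <- (b$ci_high - b$ci_low) / 2
  expect_equal(grid[which.min(hw)], xbar)
  expect_false(any(b$extrapolated))
  expect_warning(predict_with_band(f, max(x) + 1), "beyond")

  # noiseless data: the band collapses
  yy <- 0.2 + 0.4 * x
  f0 <- fit_gls_varexp(x, yy + rnorm(200, 0, 1e-8), delta = 0)
  b0 <- predict_with_band(f0, grid)
  expect_lt(max(b0$ci_high - b0$ci_low), 1e-7)
})

test_that("analytic band agrees with a parametric bootstrap", {
  set.seed(37)
  x <- runif(300, 0, 3)
  y <- 0.2 + 0.3 * x + rnorm(300, 0, 0.5 * exp(0.2 * x))
  f <- fit_gls_varexp(x, y)
  grid <- seq(0.2, 2.8, length.out = 7)
  b <- predict_with_band(f, grid)
  # 2000 coefficient draws from the estimated covariance
  L <- chol(f$vcov_beta)
  draws <- matrix(rnorm(2000 * 2), 2000) %*% L
  draws <- sweep(draws, 2, f$beta, "+")
  for (k in seq_along(grid)) {
    sim <- draws[, 1] + draws[, 2] * grid[k]
    hw_boot <- diff(quantile(sim, c(0.025, 0.975))) / 2
    hw_analytic <- (b$ci_high[k] - b$ci_low[k]) / 2
    expect_lt(abs(hw_boot / hw_analytic - 1), 0.05)
  }
})

test_that("per-group trends cover the pooled and antagonist strata", {
  cfg <- synthetic_config(seed = 38L, n_studies = 80L, b_genotypes = 0.15,
                          fast = TRUE)
  d <- simulate_observations(cfg)
  tr <- trend_by_group(d)
  expect_true(all(c("pooled", "antagonist") %in% tr$group))
  expect_true(all(is.finite(tr$t)))
  expect_equal(tr$df[tr$group == "pooled"], nrow(d) - 2L)
})
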