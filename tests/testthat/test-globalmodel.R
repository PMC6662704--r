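# Global ln(Age) x TN model: fitting, bias-corrected prediction, TN~TC.

test_that("noiseless data return the generating coefficients and R2 = 1", {
  m0 <- default_global_model(); m0$s2 <- 0
  g <- generate_regression_design(n = 200, model = m0, seed = 3)
  f <- fit_global(g, age_col = "age_years", tn_col = "tn")
  expect_equal(unname(coef(f)),
               c(-3.12, -0.59, 6.46, -0.99), tolerance = 1e-8)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$s2, 0, tolerance = 1e-12)
})

test_that("coefficient recovery is unbiased to Monte-Carlo precision", {
  nrep <- 200
  est <- matrix(NA, nrep, 4)
  for (i in seq_len(nrep)) {
    g <- generate_regression_design(n = 764, seed = 5000 + i)
    est[i, ] <- coef(fit_global(g))
  }
  truth <- c(-3.12, -0.59, 6.46, -0.99)
  mc_se <- apply(est, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(est) - truth) < 2 * mc_se))
})

test_that("fitted residual variance recovers s2 = 0.28", {
  s2 <- vapply(1:200, function(i) {
    fit_global(generate_regression_design(n = 764, seed = 3000 + i))$s2
  }, numeric(1))
  # chi-square oracle: s2 ~ 0.28 * chisq(n-4)/(n-4), so the probability of
  # landing in [0.25, 0.31] is 0.963; the observed proportion must agree to
  # binomial Monte-Carlo precision
  p0 <- pchisq(0.31 * 760 / 0.28, 760) - pchisq(0.25 * 760 / 0.28, 760)
  phat <- mean(s2 >= 0.25 & s2 <= 0.31)
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 200))
  expect_gt(phat, 0.90)
  expect_equal(mean(s2), 0.28, tolerance = 0.02)
})

test_that("degenerate designs and tiny samples are refused", {
  g <- generate_regression_design(n = 50, seed = 1)
  g$tn <- 0.3
  expect_error(fit_global(g), "zero variance")
  expect_error(fit_global(generate_regression_design(n = 12, seed = 1)[1:5, ]),
               "fewer than")
})

test_that("non-positive rates are dropped with a reported count", {
  g <- generate_regression_design(n = 100, seed = 9)
  g$rate_dw_mean <- exp(g$ln_rate)
  g$rate_dw_mean[1:7] <- -g$rate_dw_mean[1:7]
  g$ln_rate <- NULL
  expect_message(f <- fit_global(g, tn_col = "tn"), "7 non-positive")
  expect_equal(f$n, 93)
  expect_equal(f$dropped_nonpositive, 7L)
})

test_that("prediction applies the lognormal bias correction", {
  m <- default_global_model()
  # age 1, TN 0: only the intercept survives
  p <- predict(m, data.frame(age_years = 1, tn = 0))
  expect_equal(p$ln_mean, -3.12)
  expect_equal(p$rate_naive, 0.0441572, tolerance = 1e-5)
  expect_equal(p$rate_corr, 0.0507928, tolerance = 1e-5)
  # full surface at age 10, TN 0.5
  p <- predict(m, data.frame(age_years = 10, tn = 0.5))
  expect_equal(p$ln_mean, -2.388305, tolerance = 1e-6)
  expect_equal(p$rate_corr, 0.105578, tolerance = 1e-5)
  expect_equal(p$var_corr, 0.0036018, tolerance = 1e-4)
  # no-correction limit and the correction inequality
  m0 <- m; m0$s2 <- 0
  p0 <- predict(m0, data.frame(age_years = 10, tn = 0.5))
  expect_equal(p0$rate_corr, p0$rate_naive)
  grid <- expand.grid(age_years = c(1, 5, 20, 48), tn = c(0.1, 0.4, 0.8))
  pp <- predict(m, grid)
  expect_true(all(pp$rate_corr >= pp$rate_naive))
  expect_true(all(pp$rate_corr > 0))
  expect_true(all(pp$var_corr >= 0))
  expect_error(predict(m, data.frame(age_years = 0, tn = 0.3)), "positive")
})

test_that("simulate draws reproduce the model surface plus noise", {
  m <- default_global_model()
  nd <- data.frame(age_years = rep(c(2, 10, 30), each = 400),
                   tn = rep(c(0.2, 0.4, 0.6), each = 400))
  s <- simulate(m, nsim = 1, seed = 11, newdata = nd)
  mu <- predict(m, nd)$ln_mean
  expect_equal(mean(s$sim_1 - mu), 0, tolerance = 0.05)
  expect_equal(var(s$sim_1 - mu), 0.28, tolerance = 0.03)
})

test_that("TN~TC ancillary regression recovers a generated line", {
  d0 <- data.frame(tc = c(1, 4, 8, 12))
  d0$tn <- 0.067 * d0$tc + 0.077
  r <- tn_from_tc(d0)
  expect_equal(r$slope, 0.067, tolerance = 1e-10)
  expect_equal(r$intercept, 0.077, tolerance = 1e-10)
  expect_error(tn_from_tc(d0[1, ]), "at least 3")
  d0$tc <- 5
  expect_error(tn_from_tc(d0), "variance")
  slopes <- vapply(1:200, function(i) {
    set.seed(400 + i)
    tc <- runif(40, 0.9, 12.3)
    tn <- 0.067 * tc + 0.077 + rnorm(40, 0, 0.05)
    tn_from_tc(data.frame(tc = tc, tn = tn))$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.067), 2 * mc_se)
})
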