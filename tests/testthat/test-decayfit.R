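# Per-core decay fits, transition age/depth, and the C:N correlation.

test_that("noiseless decay data recover the generating parameters", {
  f <- fit_decay(curve_rates(5, 0.25, 0.8, 1:40))
  expect_true(f$fits$core1$converged)
  expect_equal(unname(coef(f)[1, ]), c(5, 0.25, 0.8), tolerance = 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-8)
  # fitted curve at age 0 equals a + c
  expect_equal(predict(f, data.frame(core_id = "core1", age_years = 0)),
               5.8, tolerance = 1e-6)
})

test_that("degenerate inputs are flagged, not silently fitted", {
  # constant rates: the decaying pool is unidentifiable
  fc <- fit_decay(data.frame(core_id = "c", age_years = 1:10, rate = 2))
  expect_false(fc$fits$c$converged)
  # fewer than three distinct ages cannot support a 3-parameter fit
  f2 <- fit_decay(data.frame(core_id = "c", age_years = c(1, 1, 2),
                             rate = c(3, 3.1, 2)))
  expect_false(f2$fits$c$converged)
})

test_that("study-like noise: intervals cover and median bias is small", {
  a <- 5; b <- 0.25; cc <- 0.8
  ages <- rep(seq(1, 40, length.out = 14), 2)   # 28 points
  nrep <- 200
  covered <- matrix(NA, nrep, 3)
  est <- matrix(NA, nrep, 3)
  for (i in seq_len(nrep)) {
    set.seed(7000 + i)
    r <- (a * exp(-b * ages) + cc) * exp(rnorm(length(ages), 0, sqrt(0.28)))
    f <- fit_decay(data.frame(core_id = "x", age_years = ages, rate = r))
    s <- f$fits$x
    est[i, ] <- s$coef
    covered[i, ] <- abs(s$coef - c(a, b, cc)) <= 1.96 * s$se
  }
  # optimization succeeds in (essentially) every run
  expect_lt(mean(!is.finite(est[, 1])), 0.02)
  # 95% Wald intervals cover the truth in at least 90% of runs
  expect_true(all(colMeans(covered, na.rm = TRUE) >= 0.90))
})

test_that("recovery over cores drawn from the study priors is centred", {
  # 300 synthetic cores with truths from the generator priors; median
  # relative error of each parameter (converged fits) stays within 10%
  ages <- rep(seq(1, 40, length.out = 14), 2)
  nrep <- 300
  rel <- matrix(NA, nrep, 3)
  conv <- logical(nrep)
  for (i in seq_len(nrep)) {
    set.seed(50000 + i)
    tru <- c(exp(runif(1, log(1), log(35))), runif(1, 0.05, 0.6),
             runif(1, 0.1, 1.2))
    r <- (tru[1] * exp(-tru[2] * ages) + tru[3]) *
      exp(rnorm(length(ages), 0, sqrt(0.28)))
    f <- fit_decay(data.frame(core_id = "x", age_years = ages, rate = r))
    rel[i, ] <- (f$fits$x$coef - tru) / tru
    conv[i] <- f$fits$x$converged
  }
  expect_gt(mean(conv), 0.9)
  med <- apply(rel[conv, ], 2, median, na.rm = TRUE)
  expect_true(all(abs(med) < 0.10))
})

test_that("closed-form transition age agrees with numeric root finding", {
  thr <- tan(pi / 180)
  set.seed(31)
  n <- 1000
  a <- exp(runif(n, log(0.05), log(35)))
  b <- runif(n, 0.02, 0.8)
  ts <- transition_age(a, b = b)
  for (i in seq_len(n)) {
    if (a[i] * b[i] <= thr) {
      expect_equal(ts[i], 0)
    } else {
      root <- uniroot(function(t) a[i] * b[i] * exp(-b[i] * t) - thr,
                      c(0, 2000), tol = 1e-14)$root
      expect_equal(ts[i], root, tolerance = 1e-9)
    }
  }
})

test_that("transition age: worked value, flat limit, c-invariance, monotone in a", {
  expect_equal(transition_age(10, b = 0.3), 17.15579, tolerance = 1e-5)
  expect_equal(transition_age(0.05, b = 0.3), 0)  # a*b below tan(1 deg)
  # independent of the constant pool: only a and b enter
  f1 <- fit_decay(curve_rates(10, 0.3, 0.1, 1:30))
  f2 <- fit_decay(curve_rates(10, 0.3, 2.0, 1:30))
  expect_equal(transition_age(f1)$transition_age_y,
               transition_age(f2)$transition_age_y, tolerance = 1e-5)
  av <- seq(1, 30, by = 0.5)
  expect_true(all(diff(transition_age(av, b = 0.3)) > 0))
  expect_error(transition_age(10, b = -1), "positive")
})

test_that("transition depth inverts the age-depth map and caps at the bottom", {
  expect_equal(transition_depth(0, 25, 22), 0)
  expect_equal(transition_depth(22, 25, 22), 25)
  expect_equal(transition_depth(11.4, 25, 22), 11.4 / 22 * 25,
               tolerance = 1e-12)  # ~12.95 cm
  expect_warning(d <- transition_depth(30, 25, 22), "capped")
  expect_equal(d, 25)
})

test_that("transition age vs C:N correlation recovers a generated slope", {
  # perfectly collinear input
  cn <- c(10, 12, 14, 16)
  r <- transition_vs_cn(2 * cn - 5, cn)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_error(transition_vs_cn(c(1, 2), c(10, 12)), "at least 3")
  expect_error(transition_vs_cn(rep(5, 4), cn), "variance")
  # slope recovery: mean estimate within 2 MC SE of the generating beta
  beta <- 0.8; n_core <- 17
  slopes <- vapply(1:200, function(i) {
    set.seed(900 + i)
    x <- runif(n_core, 9, 24)
    t <- 2 + beta * x + rnorm(n_core, 0, 2)
    transition_vs_cn(t, x)$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - beta), 2 * mc_se)
})
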