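# Synthetic study generator: design shape, determinism, noise calibration,
# and the mass-balance inversion round trip.

test_that("default design reproduces the study shape", {
  d <- generate_design(seed = 42)
  expect_equal(nrow(d$slices), 42)
  expect_equal(sum(d$slices$slice_top_cm == 2), 17)
  expect_equal(nrow(d$truth), 17)          # one row per core
  # every core has exactly one sub-surface (2-6 cm) slice, all slices 4 cm
  sub <- d$slices[d$slices$slice_top_cm == 2, ]
  expect_equal(sort(sub$core_id), sort(unique(d$slices$core_id)))
  expect_true(all(d$slices$slice_bottom_cm - d$slices$slice_top_cm == 4))
  # 3 reservoirs with 6/4/7 cores
  expect_equal(length(unique(d$slices$reservoir)), 3)
  expect_equal(as.vector(table(d$truth$reservoir)[c("CDU", "FUN", "CUN")]),
               c(6, 4, 7))
})

test_that("chemistry is drawn inside the configured ranges, TN tied to TC", {
  d <- generate_design(seed = 7)
  specs <- default_reservoir_specs()
  names(specs) <- vapply(specs, `[[`, "", "name")
  for (res in names(specs)) {
    s <- d$slices[d$slices$reservoir == res, ]
    expect_true(all(s$tc_pct_start >= specs[[res]]$tc_range[1] &
                      s$tc_pct_start <= specs[[res]]$tc_range[2]))
    expect_true(all(s$tn_pct_start >= specs[[res]]$tn_range[1] &
                      s$tn_pct_start <= specs[[res]]$tn_range[2]))
  }
  expect_gt(cor(d$slices$tc_pct_start, d$slices$tn_pct_start), 0)
})

test_that("minimal design yields one sub-surface slice; infeasible depth errors", {
  d <- generate_design(tiny_specs(n_cores = 1, n_slices = 1), seed = 1)
  expect_equal(nrow(d$slices), 1)
  expect_equal(c(d$slices$slice_top_cm, d$slices$slice_bottom_cm), c(2, 6))
  bad <- list(reservoir_spec("BAD", 2000, "2016-03-01",
                             tc_range = c(2, 6), tn_range = c(0.15, 0.6),
                             n_cores = 1, mean_total_depth_cm = 12,
                             slices_per_core = 4L))
  expect_error(generate_design(bad, seed = 1), "non-overlapping")
})

test_that("seeded generation is reproducible and seeds differ", {
  d1 <- generate_design(seed = 3)
  d2 <- generate_design(seed = 3)
  expect_identical(d1, d2)
  v1 <- generate_incubation(d1, seed = 3)
  v2 <- generate_incubation(d2, seed = 3)
  expect_identical(v1, v2)
  d3 <- generate_design(seed = 4)
  expect_false(identical(d1$slices$tc_pct_start, d3$slices$tc_pct_start))
})

test_that("default incubation yields 42 x 3 x 7 = 882 vial-occasion rows", {
  d <- generate_design(seed = 2)
  v <- generate_incubation(d, seed = 2)
  expect_equal(nrow(v), 882)
  expect_equal(attr(v, "resampled"), 0L)
})

test_that("noiseless generation round-trips through the mass balance", {
  # gascalc(generate_incubation(noise = 0)) equals the generating curve,
  # for the default design and for repeated random parameter draws
  for (seed in c(1, 13, 27)) {
    nz <- zero_noise(seed)
    d <- generate_design(tiny_specs(n_cores = 4, n_slices = 3), noise = nz)
    v <- generate_incubation(d, noise = nz)
    r <- assign_ages(compute_rates(v, d$slices), d$slices)
    r <- merge(r, d$truth[, c("core_id", "a_true", "b_true", "c_true")],
               by = "core_id")
    truth <- r$a_true * exp(-r$b_true * r$age_years) + r$c_true
    truth[r$gas == "CO2"] <- 2 * truth[r$gas == "CO2"]
    expect_lt(max(abs(r$rate_c - truth) / truth), 1e-9)
  }
})

test_that("replicate noise realizes the configured 8.6% CV", {
  ns <- noise_spec(replicate_cv = 0.086, ln_residual_sd = 0, seed = 8)
  d <- generate_design(tiny_specs(n_cores = 1, n_slices = 1), noise = ns)
  sched <- data.frame(occasion = 1, day_start = 1, day_end = 15)
  v <- generate_incubation(d, noise = ns, schedule = sched,
                           n_replicates = 10000)
  r <- compute_rates(v, d$slices, gases = "CH4")
  cv <- sd(r$rate_dw) / mean(r$rate_dw)
  expect_lt(abs(cv - 0.086) / 0.086, 0.05)
})

test_that("regression design generator matches its surface and variance", {
  g <- generate_regression_design(n = 764, seed = 5)
  expect_equal(nrow(g), 764)
  expect_identical(g, generate_regression_design(n = 764, seed = 5))
  expect_true(all(g$age_years >= 1 & g$age_years <= 48))
  expect_true(all(g$tn >= 0.1 & g$tn <= 0.8))
  # zero noise: ln rates sit exactly on the model surface
  m0 <- default_global_model(); m0$s2 <- 0
  g0 <- generate_regression_design(n = 50, model = m0, seed = 5)
  mu <- predict(m0, data.frame(age_years = g0$age_years, tn = g0$tn))$ln_mean
  expect_equal(g0$ln_rate, mu, tolerance = 1e-12)
  # large n: residual variance converges to s2 = 0.28
  gl <- generate_regression_design(n = 1e5, seed = 6)
  mu <- predict(default_global_model(),
                data.frame(age_years = gl$age_years, tn = gl$tn))$ln_mean
  expect_lt(abs(var(gl$ln_rate - mu) - 0.28), 0.01)
  expect_error(generate_regression_design(n = 5), "at least 10")
  expect_error(generate_regression_design(age_range = c(-1, 10)),
               "positive")
})
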