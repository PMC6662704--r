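# Vial mass balance: solubilities, gas amounts, dilution, rates, pooling.

test_that("solubility coefficients match the cited parameterizations", {
  # frozen from direct evaluation of the Bunsen / K0 coefficient sets
  expect_equal(henry_solubility("CH4", 298.15), 1.406973e-3,
               tolerance = 1e-6)
  expect_equal(henry_solubility("CO2", 298.15), 3.396652e-2,
               tolerance = 1e-6)
  # colder water dissolves more gas
  expect_gt(henry_solubility("CH4", 278.15), henry_solubility("CH4", 298.15))
  # monotone decreasing on a 0-40 C grid, both gases
  grid <- seq(273.15, 312.15, by = 1)
  for (g in c("CH4", "CO2")) {
    expect_true(all(diff(henry_solubility(g, grid)) < 0))
  }
  expect_error(henry_solubility("CH4", 350), "271")
  expect_error(henry_solubility("CH4", 250), "271")
})

test_that("total gas amount follows ideal-gas plus Henry partitioning", {
  # hand calculation: 1000 ppm, 1 atm, 298.15 K, 45 mL headspace, 12 mL liquid
  amt <- total_gas_amount(1000e-6, 1, 0.045, 0.012)
  expect_equal(amt, 1.856224, tolerance = 1e-6)
  # headspace term alone: x*P*V/(R*T)
  expect_equal(total_gas_amount(1000e-6, 1, 0.045, 1e-12), 1.83934,
               tolerance = 1e-5)
  expect_equal(total_gas_amount(0, 1, 0.045, 0.012), 0)
  # linear in mixing ratio
  expect_equal(total_gas_amount(2000e-6, 1, 0.045, 0.012), 2 * amt)
  expect_error(total_gas_amount(1.2, 1, 0.045, 0.012), "mole fraction")
})

test_that("dilution factor is the pressure ratio with ordering enforced", {
  expect_equal(dilution_factor(1.00, 1.17), 1.17)
  expect_equal(dilution_factor(1.00, 1.00), 1.0)
  expect_error(dilution_factor(1.00, 0.95), "pressure")
  expect_error(dilution_factor(0, 1), "positive")
})

test_that("formation rate is the signed amount difference per time and mass", {
  r <- formation_rate(4, 10, 14, dry_mass_g = 2, carbon_mass_g = 0.5)
  expect_equal(r$rate_c, 6 / 14 / 0.5, tolerance = 1e-12)
  expect_equal(formation_rate(5, 5, 10, 1, 1)$rate_dw, 0)
  # negative net rates are retained, sign-symmetric
  expect_equal(formation_rate(10, 4, 14, 2, 0.5)$rate_c,
               -formation_rate(4, 10, 14, 2, 0.5)$rate_c)
  expect_error(formation_rate(1, 2, 0, 1, 1), "dt_days")
})

test_that("rate_dw / rate_c ratio equals the carbon fraction on full tables", {
  nz <- zero_noise(11)
  d <- generate_design(tiny_specs(n_cores = 2, n_slices = 3), noise = nz)
  v <- generate_incubation(d, noise = nz)
  r <- assign_ages(compute_rates(v, d$slices), d$slices)
  expect_equal(r$rate_dw, r$rate_c * r$tc_interp / 100, tolerance = 1e-9)
})

test_that("exclusion rule flags only leading occasions of deep slow slices", {
  nz <- zero_noise(5)
  d <- generate_design(tiny_specs(n_cores = 3, n_slices = 2), noise = nz)
  # force the deep slices to look oxygen-delayed: background below threshold
  d$truth$c_true <- 0.05
  d$truth$b_true <- 0.5
  v <- generate_incubation(d, noise = nz)
  r <- assign_ages(compute_rates(v, d$slices), d$slices)

  r0 <- apply_exclusions(r, k = 0)
  expect_false(any(r0$excluded))

  r2 <- apply_exclusions(r, k = 2, threshold = 0.5)
  deep <- r2$slice_top_cm > 2
  expect_false(any(r2$excluded[!deep]))          # never the 2-6 cm layer
  expect_true(all(r2$excluded[deep & r2$occasion <= 2]))
  expect_false(any(r2$excluded[r2$occasion > 2]))
  # per deep slice: 2 occasions x 3 replicates x 2 gases flagged
  one <- r2[r2$slice_id == r2$slice_id[deep][1], ]
  expect_equal(sum(one$excluded), 12)
  expect_equal(sum(!one$excluded), nrow(one) - 12)
})

test_that("replicate pooling returns arithmetic mean and sd per group", {
  base <- data.frame(slice_id = "s", occasion = 1, gas = "CH4",
                     reservoir = "R", core_id = "c", day_mid = 5,
                     age_years = 1, tc_interp = 3, tn_interp = 0.3,
                     excluded = FALSE, rate_dw = c(0.9, 1.0, 1.1) * 0.03)
  base$rate_c <- c(0.9, 1.0, 1.1)
  p <- pool_replicates(base)
  expect_equal(p$rate_c_mean, 1.0)
  expect_equal(p$rate_c_sd, 0.1)
  expect_equal(p$n_replicates, 3L)
  single <- base[1, ]
  expect_warning(ps <- pool_replicates(single), "single replicate")
  expect_equal(ps$rate_c_mean, 0.9)
  expect_equal(ps$rate_c_sd, 0)
})
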