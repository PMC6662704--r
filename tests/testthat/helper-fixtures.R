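# Small in-code fixtures shared across test files.

tiny_specs <- function(n_cores = 1, n_slices = 2) {
  list(reservoir_spec("TST", 2000, "2016-03-01", "test",
                      tc_range = c(2, 6), tn_range = c(0.15, 0.6),
                      water_range = c(0.5, 0.8), n_cores = n_cores,
                      mean_total_depth_cm = 40,
                      slices_per_core = rep(as.integer(n_slices), n_cores)))
}

zero_noise <- function(seed = 1) {
  noise_spec(replicate_cv = 0, ln_residual_sd = 0, seed = seed)
}

# rates table for one core generated straight from the decay curve
curve_rates <- function(a, b, c, ages, core_id = "core1") {
  data.frame(core_id = core_id, age_years = ages,
             rate = a * exp(-b * ages) + c)
}
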