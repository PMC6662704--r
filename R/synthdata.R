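# Seeded synthetic study generator: reservoirs -> cores -> slices -> raw
# vial observations. The generator draws true per-core decay parameters,
# evaluates the decay curve at each occasion's midpoint age, applies ln-scale
# and replicate noise, and then inverts the vial mass balance so that running
# compute_rates()/assign_ages() on its output recovers the noisy rates
# exactly. Every draw flows from one integer seed.

#' Reservoir specification for the synthetic generator
#'
#' @param name Short reservoir label.
#' @param closure_year Calendar year of dam closure.
#' @param sampling_date Sampling date (ISO string or `Date`).
#' @param trophic_label Free-text trophic status.
#' @param tc_range,tn_range Total carbon / total nitrogen bounds (mass %,
#'   `c(min, max)`, min > 0) within which slice chemistry is drawn.
#' @param water_range Water-content bounds (mass fraction of wet sediment).
#' @param n_cores Number of cores.
#' @param mean_total_depth_cm Mean sediment depth (cm) around which per-core
#'   depths are drawn.
#' @param slices_per_core Integer vector (length `n_cores`) of slices per
#'   core, each between 1 and 4.
#' @return A `reservoir_spec` list.
#' @export
reservoir_spec <- function(name, closure_year, sampling_date,
                           trophic_label = "", tc_range, tn_range,
                           water_range = c(0.4, 0.9), n_cores,
                           mean_total_depth_cm,
                           slices_per_core = rep(2L, n_cores)) {
  stopifnot(n_cores >= 1, length(slices_per_core) == n_cores,
            all(slices_per_core >= 1), all(slices_per_core <= 4))
  for (r in list(tc_range, tn_range, water_range)) {
    if (length(r) != 2 || r[1] <= 0 || r[1] > r[2]) {
      stop("ranges must be c(min, max) with 0 < min <= max", call. = FALSE)
    }
  }
  if (closure_year >= as.integer(format(as.Date(sampling_date), "%Y"))) {
    stop("closure_year must precede the sampling year", call. = FALSE)
  }
  structure(list(name = name, closure_year = closure_year,
                 sampling_date = as.Date(sampling_date),
                 trophic_label = trophic_label, tc_range = tc_range,
                 tn_range = tn_range, water_range = water_range,
                 n_cores = as.integer(n_cores),
                 mean_total_depth_cm = mean_total_depth_cm,
                 slices_per_core = as.integer(slices_per_core)),
            class = "reservoir_spec")
}

#' Default three-reservoir study design
#'
#' Emulates a three-reservoir tropical incubation study: an oligotrophic
#' reservoir closed in 1994 (CDU, 6 cores), a eutrophic one closed in 1969
#' (FUN, 4 cores, deep deltaic sediment) and a mesotrophic Amazonian one
#' closed in 1977 (CUN, 7 cores). Chemistry bounds follow the reported
#' per-reservoir TC/TN/water ranges; the per-core slice allocation yields 42
#' slices of which 17 sample the 2-6 cm sub-surface layer.
#'
#' @return List of three [reservoir_spec()] objects.
#' @export
default_reservoir_specs <- function() {
  list(
    reservoir_spec("CDU", 1994, "2016-03-07", "oligotrophic",
                   tc_range = c(0.9, 10.2), tn_range = c(0.1, 0.8),
                   water_range = c(0.48, 0.81), n_cores = 6,
                   mean_total_depth_cm = 30,
                   slices_per_core = rep(2L, 6)),
    reservoir_spec("FUN", 1969, "2016-03-14", "eutrophic",
                   tc_range = c(1.8, 4.0), tn_range = c(0.2, 0.4),
                   water_range = c(0.53, 0.81), n_cores = 4,
                   mean_total_depth_cm = 120,
                   slices_per_core = c(4L, 4L, 4L, 3L)),
    reservoir_spec("CUN", 1977, "2016-02-24", "mesotrophic",
                   tc_range = c(2.3, 12.3), tn_range = c(0.1, 0.8),
                   water_range = c(0.42, 0.87), n_cores = 7,
                   mean_total_depth_cm = 35,
                   slices_per_core = c(3L, rep(2L, 6)))
  )
}

#' Noise specification for the synthetic generator
#'
#' @param replicate_cv Coefficient of variation among replicate vials of the
#'   same slice-occasion (multiplicative lognormal, mean 1). Default 0.086,
#'   the observed mean replicate sd of 8.6 % of the mean.
#' @param ln_residual_sd Standard deviation of the ln-scale slice-occasion
#'   residual shared across replicates. Default `sqrt(0.28)`, matching the
#'   residual variance of the global ln-rate model.
#' @param seed Integer seed from which all generator substreams derive.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(replicate_cv = 0.086, ln_residual_sd = sqrt(0.28),
                       seed = 1L) {
  stopifnot(replicate_cv >= 0, ln_residual_sd >= 0)
  structure(list(replicate_cv = replicate_cv,
                 ln_residual_sd = ln_residual_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default seven-occasion sampling schedule
#'
#' Day windows of the seven roughly two-week sampling occasions spread over a
#' 739-day incubation.
#'
#' @return `data.frame` with `occasion`, `day_start`, `day_end`.
#' @export
default_occasion_schedule <- function() {
  data.frame(occasion = 1:7,
             day_start = c(1, 9, 72, 185, 275, 423, 719),
             day_end = c(9, 28, 91, 200, 290, 442, 736))
}

# Non-overlapping 4 cm slice intervals: one sub-surface slice at 2-6 cm,
# the deepest slice just above the soil interface, intermediates spread
# evenly in between.
place_slices <- function(total_depth_cm, n_slices) {
  n_deeper <- n_slices - 1
  min_depth <- if (n_deeper == 0) 6 else if (n_deeper == 1) 10 else
    10 + 4 * n_deeper
  if (total_depth_cm < min_depth) {
    stop(sprintf("total depth %.0f cm cannot hold %d non-overlapping 4 cm slices",
                 total_depth_cm, n_slices), call. = FALSE)
  }
  tops <- 2
  if (n_deeper > 0) {
    tops <- c(tops, round(seq(6, total_depth_cm - 4,
                              length.out = n_deeper + 1)[-1]))
  }
  data.frame(slice_top_cm = tops, slice_bottom_cm = tops + 4)
}

#' Generate a synthetic slice table and its generating truth
#'
#' Draws, per core, a total sediment depth, true decay parameters
#' `(a, b, c)` of the CH4-vs-age curve, and per-slice chemistry: TC uniform
#' within the reservoir's range and TN tied to TC through
#' `TN = 0.067 TC + 0.077` plus noise (resampled, never clipped, until it
#' falls in the reservoir's TN range). End-of-incubation TC/TN decline
#' exponentially at literature rates (0.10 and 0.16 yr^-1) so that the
#' analysis-side linear interpolation is an approximation, as with real data.
#'
#' @param specs List of [reservoir_spec()] objects.
#' @param noise A [noise_spec()]; only its `seed` is used here.
#' @param seed Integer seed (defaults to `noise$seed`).
#' @param duration_days Incubation length used for end chemistry.
#' @return List with `slices` (one row per slice) and `truth` (one row per
#'   core: `a_true`, `b_true`, `c_true`, geometry).
#' @export
generate_design <- function(specs = default_reservoir_specs(),
                            noise = noise_spec(), seed = noise$seed,
                            duration_days = 739) {
  set.seed(seed)
  slices <- list()
  truth <- list()
  dur_y <- duration_days / 365
  for (sp in specs) {
    res_age <- reservoir_age_years(sp$closure_year, sp$sampling_date)
    for (ci in seq_len(sp$n_cores)) {
      core_id <- sprintf("%s_%02d", sp$name, ci)
      n_sl <- sp$slices_per_core[ci]
      min_depth <- if (n_sl == 1) 6 else if (n_sl == 2) 10 else
        10 + 4 * (n_sl - 1)
      if (sp$mean_total_depth_cm < min_depth) {
        stop(sprintf(
          "reservoir %s: mean depth %.0f cm cannot hold %d non-overlapping 4 cm slices",
          sp$name, sp$mean_total_depth_cm, n_sl), call. = FALSE)
      }
      depth <- max(min_depth,
                   round(sp$mean_total_depth_cm * stats::runif(1, 0.7, 1.3)))
      a <- exp(stats::runif(1, log(1), log(35)))
      b <- stats::runif(1, 0.05, 0.6)
      cc <- stats::runif(1, 0.1, 1.2)
      truth[[core_id]] <- data.frame(
        reservoir = sp$name, core_id = core_id, a_true = a, b_true = b,
        c_true = cc, total_depth_cm = depth, n_slices = n_sl,
        reservoir_age_y = res_age, stringsAsFactors = FALSE)
      geom <- place_slices(depth, n_sl)
      for (si in seq_len(nrow(geom))) {
        water <- stats::runif(1, sp$water_range[1], sp$water_range[2])
        tc <- stats::runif(1, sp$tc_range[1], sp$tc_range[2])
        tn <- NA_real_
        for (it in 1:1000) {
          tn <- 0.067 * tc + 0.077 + stats::rnorm(1, 0, 0.04)
          if (tn >= sp$tn_range[1] && tn <= sp$tn_range[2]) break
          tn <- NA_real_
        }
        if (is.na(tn)) {
          stop("could not draw TN inside the configured range", call. = FALSE)
        }
        water_added <- if (water < 0.65) 5 else 2.5
        slices[[paste(core_id, si)]] <- data.frame(
          reservoir = sp$name, core_id = core_id,
          slice_id = sprintf("%s_s%03d", core_id, geom$slice_top_cm[si]),
          slice_top_cm = geom$slice_top_cm[si],
          slice_bottom_cm = geom$slice_bottom_cm[si],
          total_depth_cm = depth, closure_year = sp$closure_year,
          sampling_date = as.character(sp$sampling_date),
          reservoir_age_y = res_age, water_content_frac = water,
          tc_pct_start = tc, tn_pct_start = tn,
          tc_pct_end = tc * exp(-0.10 * dur_y),
          tn_pct_end = tn * exp(-0.16 * dur_y),
          dry_mass_g = 10 * (1 - water), water_added_ml = water_added,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(slices = do.call(rbind, c(slices, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate raw vial observations by inverting the mass balance
#'
#' For every slice, occasion and replicate, evaluates the true decay curve
#' `a exp(-b age) + c` at the occasion-midpoint age, applies the ln-scale
#' slice-occasion residual (shared across replicates) and the multiplicative
#' replicate noise, and converts the resulting carbon-normalized rate back
#' into raw observables (start/end headspace ppm at the given pressures and
#' volumes) through the same Henry's-law mass balance that [compute_rates()]
#' applies forward. CO2 is emitted alongside CH4 with twice the CH4 rate and
#' its own noise draws. Noise is multiplicative, so synthetic amounts are
#' positive by construction; a defensive resampling loop (never clipping)
#' guards the inversion and logs any resampling in the `"resampled"`
#' attribute.
#'
#' @param design Output of [generate_design()] (or a list with `slices` and
#'   `truth`).
#' @param noise A [noise_spec()].
#' @param schedule Occasion day windows, as [default_occasion_schedule()].
#' @param n_replicates Replicate vials per slice.
#' @param temp_K Incubation temperature (25 C default).
#' @param pressure_before_atm Vial pressure before the N2 addition.
#' @param n2_added_ml N2 volume added before each measurement; sets the
#'   post-addition pressure.
#' @param baseline_ppm Headspace CH4 mixing ratio at occasion start (the CO2
#'   baseline is twice this).
#' @param seed Integer seed (defaults to `noise$seed`).
#' @return Vial table, one row per slice-replicate-occasion, in the dialect
#'   consumed by [compute_rates()].
#' @export
generate_incubation <- function(design, noise = noise_spec(),
                                schedule = default_occasion_schedule(),
                                n_replicates = 3, temp_K = 298.15,
                                pressure_before_atm = 1.0, n2_added_ml = 8,
                                baseline_ppm = 200, seed = noise$seed) {
  slices <- design$slices
  truth <- design$truth
  set.seed(seed + 1L)
  t_total <- max(schedule$day_end)
  kh <- c(CH4 = henry_solubility("CH4", temp_K),
          CO2 = henry_solubility("CO2", temp_K))
  sig_rep <- sqrt(log(1 + noise$replicate_cv^2))
  rows <- vector("list", nrow(slices) * nrow(schedule))
  ri <- 0L
  n_resampled <- 0L
  for (i in seq_len(nrow(slices))) {
    sl <- slices[i, ]
    tr <- truth[truth$core_id == sl$core_id, ]
    mid_depth <- (sl$slice_top_cm + sl$slice_bottom_cm) / 2
    headspace_ml <- 60 - 10 - sl$water_added_ml
    liquid_ml <- sl$water_added_ml + 10 * sl$water_content_frac
    p_after <- pressure_before_atm * (1 + n2_added_ml / headspace_ml)
    dil <- p_after / pressure_before_atm
    # µmol of gas per unit measured mole fraction, by gas
    q <- dil * pressure_before_atm *
      (headspace_ml / 1000 / (.R_GAS * temp_K) + kh * liquid_ml / 1000) * 1e6
    for (o in seq_len(nrow(schedule))) {
      d0 <- schedule$day_start[o]; d1 <- schedule$day_end[o]
      day_mid <- (d0 + d1) / 2
      age <- sample_age(mid_depth, sl$total_depth_cm, sl$reservoir_age_y,
                        incubation_days = day_mid)
      tc_t <- interpolate_chem(sl$tc_pct_start, sl$tc_pct_end,
                               sl$tn_pct_start, sl$tn_pct_end,
                               day_mid, t_total)$tc
      carbon_mass <- sl$dry_mass_g * tc_t / 100
      true_rate <- c(CH4 = tr$a_true * exp(-tr$b_true * age) + tr$c_true)
      true_rate["CO2"] <- 2 * true_rate["CH4"]
      base <- c(CH4 = baseline_ppm, CO2 = 2 * baseline_ppm) * 1e-6
      ppm <- matrix(NA_real_, 2, 2 * n_replicates,
                    dimnames = list(c("CH4", "CO2"), NULL))
      for (g in c("CH4", "CO2")) {
        for (attempt in 1:100) {
          eps <- if (noise$ln_residual_sd > 0)
            stats::rnorm(1, 0, noise$ln_residual_sd) else 0
          repf <- if (sig_rep > 0)
            exp(stats::rnorm(n_replicates, 0, sig_rep) - sig_rep^2 / 2)
          else rep(1, n_replicates)
          rate <- true_rate[g] * exp(eps) * repf
          amt0 <- base[g] * q[g]
          amt1 <- amt0 + rate * carbon_mass * (d1 - d0)
          if (all(amt1 >= 0)) break
          n_resampled <- n_resampled + 1L
        }
        if (any(amt1 < 0)) {
          stop("could not generate non-negative amounts; noise too large",
               call. = FALSE)
        }
        ppm[g, ] <- c(rep(base[g] * 1e6, n_replicates), amt1 / q[g] * 1e6)
      }
      for (r in seq_len(n_replicates)) {
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          core_id = sl$core_id, slice_id = sl$slice_id, replicate = r,
          occasion = o, day_start = d0, day_end = d1, temp_K = temp_K,
          pressure_before_atm = pressure_before_atm,
          pressure_after_atm = p_after, headspace_ml = headspace_ml,
          liquid_ml = liquid_ml,
          ch4_ppm_start = ppm["CH4", r],
          ch4_ppm_end = ppm["CH4", n_replicates + r],
          co2_ppm_start = ppm["CO2", r],
          co2_ppm_end = ppm["CO2", n_replicates + r],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  attr(out, "resampled") <- n_resampled
  out
}

#' Generate a synthetic dataset for the global ln(Age) x TN model
#'
#' Draws covariates and ln-scale rates from a [fit_global()]-style model:
#' ages log-uniform over `age_range`, TN uniform over `tn_range`, and
#' `ln_rate` equal to the model surface plus Gaussian noise with variance
#' `model$s2`.
#'
#' @param n Number of observations (>= 10).
#' @param age_range Age bounds in years (both > 0).
#' @param tn_range TN bounds in mass %.
#' @param model A `ch4_global` object supplying coefficients and `s2`
#'   (default [default_global_model()]).
#' @param seed Integer seed.
#' @return `data.frame` with `age_years`, `tn`, `ln_rate`.
#' @export
generate_regression_design <- function(n = 764, age_range = c(1, 48),
                                       tn_range = c(0.1, 0.8),
                                       model = default_global_model(),
                                       seed = 1L) {
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (any(age_range <= 0)) stop("ages must be positive", call. = FALSE)
  set.seed(seed)
  age <- exp(stats::runif(n, log(age_range[1]), log(age_range[2])))
  tn <- stats::runif(n, tn_range[1], tn_range[2])
  mu <- global_surface(model, age, tn)
  eps <- if (model$s2 > 0) stats::rnorm(n, 0, sqrt(model$s2)) else 0
  data.frame(age_years = age, tn = tn, ln_rate = mu + eps)
}
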