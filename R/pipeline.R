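# End-to-end orchestration: synthetic (or user-supplied) raw tables ->
# rates -> ages -> exclusions -> replicate pooling -> per-core decay fits,
# transition ages/depths, lifetime integration and reservoir summaries ->
# global ln(Age) x TN model. One seed drives every random draw.

#' Pipeline configuration
#'
#' Assembles (and validates) the nested configuration consumed by
#' [run_ch4_pipeline()]. Every argument has the study default; unknown keys
#' passed through `...` are rejected.
#'
#' @param seed Integer seed for all randomness.
#' @param specs Reservoir specifications ([default_reservoir_specs()]).
#' @param noise [noise_spec()]; its seed is tied to `seed`.
#' @param schedule Occasion day windows ([default_occasion_schedule()]).
#' @param exclusion List with `k` (leading occasions to flag, 0-2) and
#'   `threshold` (µmol gC^-1 d^-1).
#' @param criterion_angle Transition-age flatness criterion, degrees.
#' @param lifetime Reservoir lifetime for integration, years.
#' @param deposition_interval Years between deposited layers.
#' @param year_length Days per year.
#' @param out_dir Optional directory to write stage CSV/JSON outputs.
#' @param ... Rejected; guards against misspelled keys.
#' @return A `ch4_config` list.
#' @export
pipeline_config <- function(seed = 1L, specs = default_reservoir_specs(),
                            noise = noise_spec(seed = seed),
                            schedule = default_occasion_schedule(),
                            exclusion = list(k = 2, threshold = 0.5),
                            criterion_angle = 179, lifetime = 100,
                            deposition_interval = 1, year_length = 365,
                            out_dir = NULL, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  noise$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), specs = specs, noise = noise,
                 schedule = schedule, exclusion = exclusion,
                 criterion_angle = criterion_angle, lifetime = lifetime,
                 deposition_interval = deposition_interval,
                 year_length = year_length, out_dir = out_dir),
            class = "ch4_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar keys (`seed`, `criterion_angle`, `lifetime`,
#' `deposition_interval`, `year_length`, `out_dir`) and the `exclusion` and
#' `noise` sub-lists may be set in the file; everything else keeps its
#' default. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` (requires the yaml package) or
#'   `.json` file.
#' @return A `ch4_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- c("seed", "criterion_angle", "lifetime",
               "deposition_interval", "year_length", "out_dir",
               "exclusion", "noise")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  args <- raw[setdiff(names(raw), c("exclusion", "noise"))]
  cfg <- do.call(pipeline_config, args)
  for (k in names(raw$exclusion)) cfg$exclusion[[k]] <- raw$exclusion[[k]]
  for (k in names(raw$noise)) cfg$noise[[k]] <- raw$noise[[k]]
  cfg
}

#' Validate raw input tables
#'
#' Schema and invariant checks on the slice and vial tables: required
#' columns, positive volumes/pressures/masses, depth ordering, day ordering,
#' non-negative mixing ratios, water content in `[0, 1]`. Never mutates the
#' data.
#'
#' @param slices,vials Data frames (or CSV paths) in the dialects of
#'   [generate_design()] and [generate_incubation()].
#' @return `data.frame` of violations (`table`, `rule`, `n`); zero rows when
#'   clean.
#' @export
validate_inputs <- function(slices, vials) {
  if (is.character(slices)) slices <- utils::read.csv(slices)
  if (is.character(vials)) vials <- utils::read.csv(vials)
  v <- list()
  note <- function(tab, rule, n) {
    if (n > 0) v[[length(v) + 1]] <<- data.frame(table = tab, rule = rule,
                                                 n = n)
  }
  slice_need <- c("reservoir", "core_id", "slice_id", "slice_top_cm",
                  "slice_bottom_cm", "total_depth_cm", "reservoir_age_y",
                  "water_content_frac", "tc_pct_start", "tn_pct_start",
                  "tc_pct_end", "tn_pct_end", "dry_mass_g")
  miss <- setdiff(slice_need, names(slices))
  note("slices", paste("missing columns:", paste(miss, collapse = ", ")),
       length(miss))
  if (!length(miss)) {
    note("slices", "slice_bottom_cm <= slice_top_cm",
         sum(slices$slice_bottom_cm <= slices$slice_top_cm))
    note("slices", "slice_bottom_cm > total_depth_cm",
         sum(slices$slice_bottom_cm > slices$total_depth_cm))
    note("slices", "water_content_frac outside [0, 1]",
         sum(slices$water_content_frac < 0 | slices$water_content_frac > 1))
    note("slices", "non-positive dry mass", sum(slices$dry_mass_g <= 0))
    note("slices", "non-positive TC/TN",
         sum(slices$tc_pct_start <= 0 | slices$tn_pct_start <= 0))
  }
  vial_need <- c("core_id", "slice_id", "replicate", "occasion",
                 "day_start", "day_end", "temp_K", "pressure_before_atm",
                 "pressure_after_atm", "headspace_ml", "liquid_ml",
                 "ch4_ppm_start", "ch4_ppm_end")
  miss <- setdiff(vial_need, names(vials))
  note("vials", paste("missing columns:", paste(miss, collapse = ", ")),
       length(miss))
  if (!length(miss)) {
    note("vials", "day_end <= day_start", sum(vials$day_end <= vials$day_start))
    note("vials", "non-positive volumes",
         sum(vials$headspace_ml <= 0 | vials$liquid_ml <= 0))
    note("vials", "pressure_after < pressure_before",
         sum(vials$pressure_after_atm < vials$pressure_before_atm))
    note("vials", "negative mixing ratios",
         sum(vials$ch4_ppm_start < 0 | vials$ch4_ppm_end < 0))
    note("vials", "unmatched slice_id",
         sum(!vials$slice_id %in% slices$slice_id))
  }
  if (!length(v)) {
    return(data.frame(table = character(), rule = character(),
                      n = integer()))
  }
  do.call(rbind, v)
}

#' Run the full sediment CH4 analysis pipeline
#'
#' Executes every stage in order on synthetic data (default) or on
#' user-supplied slice and vial tables: gas mass balance, age assignment and
#' chemistry interpolation, exclusion flagging, replicate pooling, per-core
#' decay fits with transition ages and depths, lifetime integration with the
#' beyond-transition share, per-reservoir summaries, the global
#' ln(Age) x TN model, and the ancillary TN~TC regression.
#'
#' @param config A [pipeline_config()] (or path readable by
#'   [read_pipeline_config()]).
#' @param slices,vials Optional user-supplied tables (data frames or CSV
#'   paths); when `NULL`, both are generated synthetically under
#'   `config$seed`.
#' @param strict Stop on validation violations (default) instead of
#'   warning.
#' @return An object of class `ch4_run`: all stage tables (`slices`,
#'   `vials`, `rates`, `pooled`), fitted objects (`decay`, `global`),
#'   core-level results (`cores`: transition age/depth, lifetime totals,
#'   beyond fraction), `reservoir_summary`, `tn_tc`, the generating `truth`
#'   (synthetic runs only) and a `report` of row/exclusion counts.
#' @export
run_ch4_pipeline <- function(config = pipeline_config(), slices = NULL,
                             vials = NULL, strict = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  truth <- NULL
  if (is.null(slices) || is.null(vials)) {
    design <- generate_design(config$specs, config$noise,
                              seed = config$seed)
    slices <- design$slices
    truth <- design$truth
    vials <- generate_incubation(design, config$noise,
                                 schedule = config$schedule,
                                 seed = config$seed)
  } else {
    if (is.character(slices)) slices <- utils::read.csv(slices)
    if (is.character(vials)) vials <- utils::read.csv(vials)
  }
  viol <- validate_inputs(slices, vials)
  if (nrow(viol)) {
    msg <- paste(sprintf("%s: %s (%d)", viol$table, viol$rule, viol$n),
                 collapse = "; ")
    if (strict) stop("input validation failed: ", msg, call. = FALSE)
    warning("input validation: ", msg)
  }

  rates <- compute_rates(vials, slices)
  rates <- assign_ages(rates, slices, year_length = config$year_length)
  rates <- apply_exclusions(rates, k = config$exclusion$k,
                            threshold = config$exclusion$threshold)
  pooled <- pool_replicates(rates)

  ch4 <- pooled[pooled$gas == "CH4", ]
  decay <- fit_decay(ch4)
  trans <- transition_age(decay, criterion_angle = config$criterion_angle)

  geom <- unique(slices[, c("core_id", "reservoir", "total_depth_cm",
                            "reservoir_age_y")])
  cores <- merge(trans, geom, by = "core_id", sort = FALSE)
  cores$transition_depth_cm <- NA_real_
  cores$total_ch4 <- NA_real_
  cores$beyond_fraction <- NA_real_
  for (i in seq_len(nrow(cores))) {
    if (!cores$converged[i] || !is.finite(cores$transition_age_y[i])) next
    cores$transition_depth_cm[i] <- transition_depth(
      cores$transition_age_y[i], cores$total_depth_cm[i],
      cores$reservoir_age_y[i])
    li <- integrate_lifetime(cores$a[i], cores$b[i], cores$c[i],
                             cores$transition_age_y[i],
                             lifetime = config$lifetime,
                             deposition_interval = config$deposition_interval,
                             year_length = config$year_length)
    cores$total_ch4[i] <- li$total_ch4
    cores$beyond_fraction[i] <- li$beyond_fraction
  }
  reservoir_summary <- summarize_reservoirs(cores[cores$converged, ])

  global <- fit_global(ch4[!ch4$excluded, ])
  tn_tc <- tn_from_tc(slices, tc_col = "tc_pct_start",
                      tn_col = "tn_pct_start")

  report <- list(
    seed = config$seed,
    n_vial_rows = nrow(vials),
    n_rate_rows = nrow(rates),
    n_excluded = sum(rates$excluded),
    n_used = sum(!rates$excluded),
    n_pooled = nrow(pooled),
    n_cores = nrow(cores),
    n_converged = sum(cores$converged),
    n_dropped_nonpositive = global$dropped_nonpositive,
    package_version = as.character(utils::packageVersion("sedch4"))
  )
  stopifnot(report$n_excluded + report$n_used == report$n_rate_rows)

  run <- structure(list(config = config, slices = slices, vials = vials,
                        rates = rates, pooled = pooled, decay = decay,
                        cores = cores,
                        reservoir_summary = reservoir_summary,
                        global = global, tn_tc = tn_tc, truth = truth,
                        report = report),
                   class = "ch4_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
  wcsv(run$slices, "slices.csv")
  wcsv(run$vials, "vials.csv")
  wcsv(run$rates, "rates.csv")
  wcsv(run$pooled, "rates_pooled.csv")
  wcsv(summary(run$decay), "decay_fits.csv")
  wcsv(run$cores, "transition.csv")
  wcsv(run$reservoir_summary, "reservoir_summary.csv")
  if (!is.null(run$truth)) wcsv(run$truth, "truth.csv")
  gm <- run$global
  jsonlite::write_json(
    list(coefficients = as.list(gm$coefficients), s2 = gm$s2, r2 = gm$r2,
         n = gm$n, seed = run$report$seed),
    file.path(out_dir, "global_model.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.ch4_run <- function(x, digits = 3, ...) {
  r <- x$report
  cat("Sediment CH4 formation pipeline run (seed", r$seed, ")\n")
  cat(sprintf("vial rows %d | rate rows %d (excluded %d) | cores %d (%d converged)\n",
              r$n_vial_rows, r$n_rate_rows, r$n_excluded, r$n_cores,
              r$n_converged))
  cat("\nPer-reservoir summary (mean +/- sd across cores):\n")
  s <- x$reservoir_summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s: transition %.1f +/- %.1f y, depth %.0f +/- %.0f cm, beyond share %.0f +/- %.0f %%\n",
                s$reservoir[i], s$transition_age_y_mean[i],
                s$transition_age_y_sd[i], s$transition_depth_cm_mean[i],
                s$transition_depth_cm_sd[i],
                100 * s$beyond_fraction_mean[i],
                100 * s$beyond_fraction_sd[i]))
  }
  cat("\nGlobal model: ")
  print(round(coef(x$global), digits))
  cat(sprintf("s2 = %.3f  R2 = %.3f  n = %d\n", x$global$s2, x$global$r2,
              x$global$n))
  invisible(x)
}
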