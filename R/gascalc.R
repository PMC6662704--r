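# Headspace gas mass balance: mixing ratios + pressures + volumes -> amounts
# -> net formation rates. Pressures in atm, volumes in L internally; ppm and
# mL are accepted at the table boundary (compute_rates).

# ideal gas constant, L atm mol^-1 K^-1
.R_GAS <- 0.082057
# molar volume of an ideal gas at STP (273.15 K, 1 atm), L mol^-1
.V_STP <- 22.414

# Bunsen solubility of CH4 in water (Wiesenburg & Guinasso parameterization):
# ln(beta) = A1 + A2*(100/T) + A3*ln(T/100) + S*(B1 + B2*(T/100) + B3*(T/100)^2)
.CH4_BUNSEN_A <- c(-67.1962, 99.1624, 27.9015)
.CH4_BUNSEN_B <- c(-0.072909, 0.041674, -0.0064603)

# CO2 solubility K0 in mol L^-1 atm^-1 (Weiss parameterization), same form
.CO2_K0_A <- c(-58.0931, 90.5069, 22.2940)
.CO2_K0_B <- c(0.027766, -0.025888, 0.0050578)

#' Henry-type solubility coefficient for CH4 or CO2 in water
#'
#' Returns the solubility of methane or carbon dioxide in (fresh or saline)
#' water as a Henry-type coefficient in mol L^-1 atm^-1. Methane uses the
#' Bunsen solubility parameterization of Wiesenburg & Guinasso, converted to
#' molar units by division with the molar volume of an ideal gas at STP;
#' carbon dioxide uses the Weiss K0 parameterization, which is already in
#' mol L^-1 atm^-1. No carbonate speciation is applied to CO2: the
#' coefficient describes dissolved free CO2 only.
#'
#' @param gas `"CH4"` or `"CO2"`.
#' @param temp_K Water temperature in kelvin; must lie in (271, 313), the
#'   range over which the parameterizations are used here.
#' @param salinity Salinity in per mil; 0 (freshwater) by default.
#' @return Solubility in mol L^-1 atm^-1 (numeric, vectorized over `temp_K`).
#' @examples
#' henry_solubility("CH4", 298.15)  # ~1.4e-3 mol/L/atm
#' henry_solubility("CO2", 298.15)  # ~3.4e-2 mol/L/atm
#' @export
henry_solubility <- function(gas = c("CH4", "CO2"), temp_K = 298.15,
                             salinity = 0) {
  gas <- match.arg(gas)
  if (any(!is.finite(temp_K)) || any(temp_K <= 271) || any(temp_K >= 313)) {
    stop("temp_K must lie in (271, 313) K", call. = FALSE)
  }
  if (any(salinity < 0)) stop("salinity must be >= 0", call. = FALSE)
  th <- temp_K / 100
  if (gas == "CH4") {
    A <- .CH4_BUNSEN_A; B <- .CH4_BUNSEN_B
    bunsen <- exp(A[1] + A[2] / th + A[3] * log(th) +
                    salinity * (B[1] + B[2] * th + B[3] * th^2))
    bunsen / .V_STP
  } else {
    A <- .CO2_K0_A; B <- .CO2_K0_B
    exp(A[1] + A[2] / th + A[3] * log(th) +
          salinity * (B[1] + B[2] * th + B[3] * th^2))
  }
}

#' Total gas amount in a sealed vial (headspace + dissolved)
#'
#' Computes the total amount of a gas in a shaken, equilibrated vial from its
#' headspace mixing ratio: the headspace pool via the ideal gas law plus the
#' dissolved pool via Henry's law,
#' `n = x * P * V_hs / (R * T) + x * P * K_H * V_liq`, in micromoles.
#'
#' @param mixing_ratio Mole fraction of the gas in the headspace (not ppm);
#'   must satisfy `0 <= x < 1`.
#' @param pressure_atm Total vial pressure in atm for this measurement stage.
#' @param headspace_L,liquid_L Headspace and liquid volumes in litres.
#' @param temp_K Temperature in kelvin.
#' @param gas `"CH4"` or `"CO2"`; used to pick the solubility coefficient
#'   unless `solubility` is supplied.
#' @param solubility Optional Henry-type coefficient in mol L^-1 atm^-1,
#'   overriding the built-in parameterizations.
#' @return Amount in micromoles (vectorized).
#' @export
total_gas_amount <- function(mixing_ratio, pressure_atm, headspace_L,
                             liquid_L, temp_K = 298.15, gas = "CH4",
                             solubility = NULL) {
  if (any(mixing_ratio < 0) || any(mixing_ratio >= 1)) {
    stop("mixing_ratio must be a mole fraction in [0, 1)", call. = FALSE)
  }
  if (any(pressure_atm <= 0) || any(headspace_L <= 0) || any(liquid_L <= 0)) {
    stop("pressures and volumes must be positive", call. = FALSE)
  }
  kh <- if (is.null(solubility)) henry_solubility(gas, temp_K) else solubility
  p_part <- mixing_ratio * pressure_atm
  1e6 * (p_part * headspace_L / (.R_GAS * temp_K) + p_part * kh * liquid_L)
}

#' Dilution factor of an N2 addition
#'
#' Adding N2 to a sealed vial before sampling dilutes the headspace; the
#' factor `pressure_after / pressure_before` multiplies measured mixing
#' ratios to undo that dilution.
#'
#' @param pressure_before,pressure_after Vial pressure in atm immediately
#'   before and after the N2 addition; `pressure_after >= pressure_before`.
#' @return Dimensionless factor >= 1 (vectorized).
#' @export
dilution_factor <- function(pressure_before, pressure_after) {
  if (any(pressure_before <= 0)) {
    stop("pressure_before must be positive", call. = FALSE)
  }
  if (any(pressure_after < pressure_before)) {
    stop("pressure_after < pressure_before: pressure must not drop on N2 addition",
         call. = FALSE)
  }
  pressure_after / pressure_before
}

#' Net formation rate from two gas amounts
#'
#' The net rate over one sampling occasion is the amount difference divided
#' by the elapsed time, normalized either per gram sediment dry weight or per
#' gram sediment carbon. Negative net rates are retained: the measurements
#' are net of any consumption and are never clipped.
#'
#' @param start_umol,end_umol Total gas amounts (µmol) at occasion start/end.
#' @param dt_days Elapsed time in days (> 0).
#' @param dry_mass_g Sediment dry mass in the vial, g.
#' @param carbon_mass_g Sediment carbon mass in the vial, g.
#' @return `data.frame` with `rate_dw` (µmol g(dw)^-1 d^-1) and `rate_c`
#'   (µmol gC^-1 d^-1).
#' @export
formation_rate <- function(start_umol, end_umol, dt_days, dry_mass_g,
                           carbon_mass_g) {
  if (any(dt_days <= 0)) stop("dt_days must be positive", call. = FALSE)
  if (any(dry_mass_g <= 0) || any(carbon_mass_g <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  d <- (end_umol - start_umol) / dt_days
  data.frame(rate_dw = d / dry_mass_g, rate_c = d / carbon_mass_g)
}

#' Per-vial net formation rates from raw incubation tables
#'
#' Runs the full vial mass balance on a table of raw headspace observations:
#' measured start/end mixing ratios are corrected for N2 dilution, converted
#' to total (headspace + dissolved) amounts at the pre-addition pressure, and
#' differenced into net rates per dry weight. Carbon-normalized rates are
#' added later by [assign_ages()], once TC has been interpolated to the
#' occasion time.
#'
#' @param vials Vial table, one row per vial-occasion (see
#'   [generate_incubation()] for the column dialect: ppm mixing ratios, atm
#'   pressures, mL volumes).
#' @param slices Slice table (see [generate_design()]); supplies dry mass per
#'   slice.
#' @param gases Which gases to compute; any of `"CH4"`, `"CO2"`.
#' @return Long `data.frame`, one row per vial-occasion-gas, with identifiers,
#'   day window (`day_start`, `day_end`, `day_mid`, `dt_days`), `gas`,
#'   amounts (`amount_start_umol`, `amount_end_umol`) and `rate_dw`.
#' @export
compute_rates <- function(vials, slices, gases = c("CH4", "CO2")) {
  gases <- match.arg(gases, several.ok = TRUE)
  need <- c("core_id", "slice_id", "replicate", "occasion", "day_start",
            "day_end", "temp_K", "pressure_before_atm", "pressure_after_atm",
            "headspace_ml", "liquid_ml")
  miss <- setdiff(need, names(vials))
  if (length(miss)) {
    stop("vials table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  v <- merge(vials,
             slices[, c("slice_id", "reservoir", "dry_mass_g")],
             by = "slice_id", sort = FALSE)
  dil <- dilution_factor(v$pressure_before_atm, v$pressure_after_atm)
  dt <- v$day_end - v$day_start
  if (any(dt <= 0)) stop("day_end must exceed day_start", call. = FALSE)
  out <- lapply(gases, function(g) {
    pcol <- if (g == "CH4") c("ch4_ppm_start", "ch4_ppm_end") else
      c("co2_ppm_start", "co2_ppm_end")
    x0 <- v[[pcol[1]]] * 1e-6 * dil
    x1 <- v[[pcol[2]]] * 1e-6 * dil
    kh <- henry_solubility(g, v$temp_K[1])
    a0 <- total_gas_amount(x0, v$pressure_before_atm, v$headspace_ml / 1000,
                           v$liquid_ml / 1000, v$temp_K, gas = g,
                           solubility = kh)
    a1 <- total_gas_amount(x1, v$pressure_before_atm, v$headspace_ml / 1000,
                           v$liquid_ml / 1000, v$temp_K, gas = g,
                           solubility = kh)
    data.frame(
      reservoir = v$reservoir, core_id = v$core_id, slice_id = v$slice_id,
      replicate = v$replicate, occasion = v$occasion,
      day_start = v$day_start, day_end = v$day_end,
      day_mid = (v$day_start + v$day_end) / 2, dt_days = dt, gas = g,
      amount_start_umol = a0, amount_end_umol = a1,
      rate_dw = (a1 - a0) / dt / v$dry_mass_g,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Flag early measurements of deep, low-activity slices
#'
#' In old, deep sediment the first one or two occasions can reflect trace
#' oxygen carried over from sample handling rather than established
#' methanogenesis. This rule flags (never deletes) the first `k` occasions of
#' slices that (a) lie below the sub-surface layer and (b) show an occasion-1
#' mean CH4 rate below `threshold`.
#'
#' @param rates Age-augmented rate table (from [assign_ages()]; needs
#'   `slice_id`, `slice_top_cm`, `occasion`, `gas`, `rate_c`).
#' @param k Number of leading occasions to flag, 0, 1 or 2.
#' @param threshold Occasion-1 mean CH4 rate (µmol gC^-1 d^-1) below which a
#'   deep slice is treated as oxygen-delayed.
#' @param subsurface_top_cm Top depth of the sub-surface layer; slices whose
#'   top is at this depth are never flagged.
#' @return `rates` with a logical `excluded` column.
#' @export
apply_exclusions <- function(rates, k = 2, threshold = 0.5,
                             subsurface_top_cm = 2) {
  if (!k %in% 0:2) stop("k must be 0, 1 or 2", call. = FALSE)
  rates$excluded <- FALSE
  if (k == 0) return(rates)
  ch4_1 <- rates[rates$gas == "CH4" & rates$occasion == 1, ]
  m1 <- tapply(ch4_1$rate_c, ch4_1$slice_id, mean)
  deep <- tapply(rates$slice_top_cm, rates$slice_id, function(x) x[1]) >
    subsurface_top_cm
  target <- names(m1)[deep[names(m1)] & m1 < threshold]
  rates$excluded <- rates$slice_id %in% target & rates$occasion <= k
  rates
}

#' Pool replicate rates to slice-occasion means
#'
#' Downstream decay and regression fits consume the arithmetic mean of the
#' (usually three) replicate vials per slice and occasion; the replicate
#' standard deviation is carried as a precision diagnostic.
#'
#' @param rates Age-augmented rate table with an `excluded` column.
#' @return One row per slice-occasion-gas with `rate_c_mean`, `rate_c_sd`,
#'   `rate_dw_mean`, `rate_dw_sd`, `n_replicates`, and the slice-level
#'   covariates (age, interpolated TC/TN, exclusion flag).
#' @export
pool_replicates <- function(rates) {
  key <- interaction(rates$slice_id, rates$occasion, rates$gas, drop = TRUE)
  one <- function(f) tapply(rates[[f]], key, function(x) x[1])
  n <- as.vector(tapply(rates$rate_c, key, length))
  if (any(n < 2)) {
    warning("some slice-occasion groups have a single replicate; sd set to 0")
  }
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  out <- data.frame(
    slice_id = as.vector(one("slice_id")),
    occasion = as.vector(one("occasion")),
    gas = as.vector(one("gas")),
    reservoir = as.vector(one("reservoir")),
    core_id = as.vector(one("core_id")),
    day_mid = as.vector(one("day_mid")),
    age_years = as.vector(one("age_years")),
    tc_interp = as.vector(one("tc_interp")),
    tn_interp = as.vector(one("tn_interp")),
    excluded = as.vector(one("excluded")),
    rate_c_mean = as.vector(tapply(rates$rate_c, key, mean)),
    rate_c_sd = as.vector(tapply(rates$rate_c, key, sd0)),
    rate_dw_mean = as.vector(tapply(rates$rate_dw, key, mean)),
    rate_dw_sd = as.vector(tapply(rates$rate_dw, key, sd0)),
    n_replicates = n,
    stringsAsFactors = FALSE
  )
  out[order(out$gas, out$slice_id, out$occasion), , drop = FALSE]
}
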