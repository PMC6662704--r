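# Global prediction model: ln(CH4 formation per dry weight) regressed on
# ln(age), TN and their interaction, with the lognormal back-transformation
# bias correction exp(ln_mean + s^2/2) applied to predictions on the rate
# scale.

# Evaluate the ln-scale model surface for a coefficient set.
global_surface <- function(model, age_years, tn) {
  b <- model$coefficients
  b[["intercept"]] + b[["ln_age"]] * log(age_years) + b[["tn"]] * tn +
    b[["ln_age_tn"]] * log(age_years) * tn
}

new_ch4_global <- function(coefficients, s2, r2, n, fit = NULL,
                           dropped_nonpositive = 0L, frozen = FALSE,
                           call = NULL) {
  stopifnot(s2 >= 0, r2 >= 0, r2 <= 1)
  structure(list(coefficients = coefficients, s2 = s2, r2 = r2, n = n,
                 fit = fit, dropped_nonpositive = dropped_nonpositive,
                 frozen = frozen, call = call),
            class = "ch4_global")
}

#' Fit the global ln(Age) x TN model of CH4 formation
#'
#' Ordinary least squares of `ln(rate) ~ ln(age) + tn + ln(age):tn` on
#' dry-weight-normalized CH4 formation rates pooled across all slices,
#' occasions and reservoirs. Rates must be positive to be ln-transformed;
#' non-positive net rates are dropped with a message reporting the count.
#'
#' @param data `data.frame` of pooled observations.
#' @param rate_col Column holding the rate in µmol g(dw)^-1 d^-1 (default
#'   `"rate_dw_mean"`; a precomputed `ln_rate` column may be supplied
#'   instead, taking precedence).
#' @param age_col,tn_col Columns holding age (years, > 0) and TN (mass %).
#' @param min_n Minimum usable observations (default 10).
#' @return An object of class `ch4_global` holding the coefficient vector
#'   (`intercept`, `ln_age`, `tn`, `ln_age_tn`), the residual variance `s2`,
#'   `r2`, `n`, and the underlying `lm` fit; methods: [coef()], [print()],
#'   [summary()], [predict()] (with bias correction), [simulate()],
#'   [residuals()].
#' @seealso [default_global_model()], [generate_regression_design()]
#' @export
fit_global <- function(data, rate_col = "rate_dw_mean",
                       age_col = "age_years", tn_col = "tn_interp",
                       min_n = 10) {
  if (!tn_col %in% names(data) && "tn" %in% names(data)) tn_col <- "tn"
  stopifnot(all(c(age_col, tn_col) %in% names(data)))
  age <- data[[age_col]]
  tn <- data[[tn_col]]
  dropped <- 0L
  if ("ln_rate" %in% names(data)) {
    ln_rate <- data$ln_rate
  } else {
    stopifnot(rate_col %in% names(data))
    rate <- data[[rate_col]]
    pos <- is.finite(rate) & rate > 0
    dropped <- sum(!pos, na.rm = TRUE)
    if (dropped > 0) {
      message(dropped,
              " non-positive or missing net rates dropped before ln transform")
    }
    ln_rate <- log(rate[pos]); age <- age[pos]; tn <- tn[pos]
  }
  ok <- is.finite(ln_rate) & is.finite(age) & is.finite(tn)
  ln_rate <- ln_rate[ok]; age <- age[ok]; tn <- tn[ok]
  if (any(age <= 0)) stop("ages must be positive", call. = FALSE)
  if (length(ln_rate) < min_n) {
    stop("fewer than ", min_n, " usable observations", call. = FALSE)
  }
  if (stats::var(tn) == 0 || stats::var(log(age)) == 0) {
    stop("degenerate design: zero variance in TN or ln(age)", call. = FALSE)
  }
  ln_age <- log(age)
  fit <- stats::lm(ln_rate ~ ln_age * tn)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear design: coefficients not estimable", call. = FALSE)
  }
  co <- stats::coef(fit)
  sm <- summary(fit)
  new_ch4_global(
    coefficients = c(intercept = unname(co["(Intercept)"]),
                     ln_age = unname(co["ln_age"]), tn = unname(co["tn"]),
                     ln_age_tn = unname(co["ln_age:tn"])),
    s2 = sm$sigma^2, r2 = sm$r.squared, n = length(ln_rate), fit = fit,
    dropped_nonpositive = dropped, call = match.call())
}

#' Frozen reference coefficient set of the global model
#'
#' The global model with the reference coefficients estimated from the
#' original three-reservoir incubation dataset: `ln(rate) = -0.59 ln(Age) +
#' 6.46 TN - 0.99 ln(Age) TN - 3.12`, residual variance `s2 = 0.28`,
#' `R^2 = 0.81`, `n = 764`, with rate in µmol g(dw)^-1 d^-1, age in years
#' and TN in mass %. Usable for prediction and as generating truth in
#' simulations; it carries no underlying `lm` fit.
#'
#' @return A `ch4_global` object.
#' @export
default_global_model <- function() {
  new_ch4_global(
    coefficients = c(intercept = -3.12, ln_age = -0.59, tn = 6.46,
                     ln_age_tn = -0.99),
    s2 = 0.28, r2 = 0.81, n = 764L, frozen = TRUE)
}

#' @export
coef.ch4_global <- function(object, ...) object$coefficients

#' @export
print.ch4_global <- function(x, digits = 4, ...) {
  cat("Global CH4 formation model: ln(rate) ~ ln(age) * TN\n")
  if (x$frozen) cat("(frozen reference coefficient set)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("s2 = %.4g  R2 = %.4g  n = %d\n", x$s2, x$r2, x$n))
  if (x$dropped_nonpositive > 0) {
    cat(x$dropped_nonpositive, "non-positive rates dropped\n")
  }
  invisible(x)
}

#' @export
summary.ch4_global <- function(object, ...) {
  if (!is.null(object$fit)) return(summary(object$fit, ...))
  print(object)
  invisible(object)
}

#' Predict CH4 formation with back-transformation bias correction
#'
#' Evaluates the ln-scale model surface and back-transforms it to the rate
#' scale. A naive `exp(ln_mean)` estimates the median of the lognormal
#' predictive distribution and underestimates its mean; the corrected rate
#' `exp(ln_mean + s2/2)` is the lognormal mean, and the corrected variance is
#' `rate_corr^2 * (exp(s2) - 1)`.
#'
#' @param object A `ch4_global` model.
#' @param newdata `data.frame` with `age_years` (> 0) and `tn` (mass %);
#'   `tn_interp` is accepted as an alias.
#' @param ... Unused.
#' @return `data.frame` with `ln_mean`, `rate_naive`, `rate_corr` (both in
#'   µmol g(dw)^-1 d^-1) and `var_corr`.
#' @examples
#' predict(default_global_model(), data.frame(age_years = 10, tn = 0.5))
#' @export
predict.ch4_global <- function(object, newdata, ...) {
  if (!"tn" %in% names(newdata) && "tn_interp" %in% names(newdata)) {
    newdata$tn <- newdata$tn_interp
  }
  stopifnot(all(c("age_years", "tn") %in% names(newdata)))
  if (any(newdata$age_years <= 0)) {
    stop("age must be positive", call. = FALSE)
  }
  ln_mean <- global_surface(object, newdata$age_years, newdata$tn)
  rate_corr <- exp(ln_mean + 0.5 * object$s2)
  data.frame(ln_mean = ln_mean, rate_naive = exp(ln_mean),
             rate_corr = rate_corr,
             var_corr = rate_corr^2 * (exp(object$s2) - 1))
}

#' @export
simulate.ch4_global <- function(object, nsim = 1, seed = NULL, newdata,
                                ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- global_surface(object, newdata$age_years, newdata$tn)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         sqrt(object$s2))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.ch4_global <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("frozen coefficient sets carry no residuals", call. = FALSE)
  }
  stats::residuals(object$fit)
}

#' Ancillary regression of TN on TC
#'
#' Least-squares line of total nitrogen on total carbon across all slices,
#' a diagnostic of how tightly the two track each other (and hence of why
#' the dry-weight-normalized rate is modelled on TN alone).
#'
#' @param data `data.frame` with TC and TN columns.
#' @param tc_col,tn_col Column names (defaults `"tc"`, `"tn"`; the
#'   `_interp`/`_pct_start` variants are accepted as fallbacks).
#' @return List with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
tn_from_tc <- function(data, tc_col = "tc", tn_col = "tn") {
  for (alt in c("tc_interp", "tc_pct_start")) {
    if (!tc_col %in% names(data) && alt %in% names(data)) tc_col <- alt
  }
  for (alt in c("tn_interp", "tn_pct_start")) {
    if (!tn_col %in% names(data) && alt %in% names(data)) tn_col <- alt
  }
  tc <- data[[tc_col]]; tn <- data[[tn_col]]
  ok <- is.finite(tc) & is.finite(tn)
  tc <- tc[ok]; tn <- tn[ok]
  if (length(tc) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(tc) == 0) stop("zero variance in TC", call. = FALSE)
  fit <- stats::lm(tn ~ tc)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), r2 = sm$r.squared,
       p = sm$coefficients[2, 4], n = length(tc))
}
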