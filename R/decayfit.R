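# Per-core exponential decay of CH4 formation with sediment age:
#   rate(age) = a * exp(-b * age) + c,   a, c >= 0, b > 0
# (one decaying pool over a constant background pool), fitted by bounded
# Levenberg-Marquardt least squares with multi-start initialization, and the
# derived "transition age" at which the modelled curve becomes effectively
# flat.

decay_curve <- function(a, b, c, age) a * exp(-b * age) + c

init_decay <- function(age, rate) {
  c0 <- max(min(rate), 0)
  a0 <- max(max(rate) - c0, 1e-6)
  # log-linear slope of the above-background part gives b0
  y <- rate - 0.99 * c0
  ok <- y > 0
  b0 <- 0.1
  if (sum(ok) >= 2 && stats::var(age[ok]) > 0) {
    sl <- stats::coef(stats::lm(log(y[ok]) ~ age[ok]))[2]
    if (is.finite(sl) && sl < 0) b0 <- -sl
  }
  c(a = a0, b = min(max(b0, 1e-3), 10), c = max(c0, 1e-6))
}

fit_decay_one <- function(age, rate, n_starts = 10, restart_seed = 1904L,
                          scale = "log") {
  st0 <- init_decay(age, rate)
  # deterministic jitter grid around the heuristic start (fixed local RNG,
  # global RNG state restored afterwards)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(restart_seed)
  jit <- matrix(exp(stats::rnorm(3 * n_starts, 0, 0.7)), ncol = 3)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  jit[1, ] <- 1
  best <- NULL
  dat <- data.frame(age = age, rate = rate, ln_rate = log(pmax(rate, 1e-300)))
  form <- if (scale == "log") {
    ln_rate ~ log(a * exp(-b * age) + c)
  } else {
    rate ~ a * exp(-b * age) + c
  }
  lower <- if (scale == "log") c(a = 0, b = 1e-8, c = 1e-12) else
    c(a = 0, b = 1e-8, c = 0)
  # jittered starts around the heuristic, plus a coarse deterministic grid
  # as a fallback when the heuristic start sits in an ill-conditioned region
  grid <- as.matrix(expand.grid(a = c(st0["a"], 2 * mean(rate)),
                                b = c(0.05, 0.2, 0.6),
                                c = c(st0["c"], max(mean(rate) / 2, 1e-6))))
  starts <- rbind(sweep(jit, 2, st0, "*"), grid)
  for (s in seq_len(nrow(starts))) {
    st <- pmax(starts[s, ], lower + 1e-12)
    names(st) <- c("a", "b", "c")
    f <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(st),
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(coef = c(a = NA_real_, b = NA_real_, c = NA_real_),
                se = c(a = NA_real_, b = NA_real_, c = NA_real_),
                rss = NA_real_, sigma2 = NA_real_, n = length(age),
                converged = FALSE, boundary = FALSE))
  }
  f <- best$fit
  co <- stats::coef(f)
  se <- tryCatch(summary(f)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  names(se) <- names(co)
  boundary <- co["b"] <= 1e-6 || co["a"] <= 1e-10
  list(coef = co, se = se, rss = best$rss,
       sigma2 = best$rss / max(length(age) - 3, 1), n = length(age),
       converged = isTRUE(f$convInfo$isConv) && !boundary,
       boundary = boundary)
}

#' Fit per-core exponential decay models of CH4 formation vs age
#'
#' Fits `rate = a * exp(-b * age) + c` independently to each core by bounded
#' nonlinear least squares (Levenberg-Marquardt, `a, c >= 0`, `b > 0`) on
#' slice-occasion replicate-mean rates. By default the least-squares
#' criterion is applied on the log scale (`ln(rate) ~ ln(a exp(-b age) +
#' c)`), matching the multiplicative error structure of replicated headspace
#' rates, whose scatter is proportional to the rate; `scale = "linear"`
#' minimizes raw-rate residuals instead. On the log scale, non-positive net
#' rates cannot enter the criterion and are dropped with a message.
#' Initialization takes `c0` as the minimum rate, `a0` as the range, and
#' `b0` from a log-linear fit of the above-background rates; ten
#' multiplicatively jittered restarts (fixed internal seed) guard against
#' local minima and the best residual sum of squares wins. Cores with fewer
#' than three distinct ages, failed optimizations, or parameters pinned at a
#' bound are flagged `converged = FALSE` (their coefficients are still
#' reported).
#'
#' @param data `data.frame` of pooled rates with columns `core_id`,
#'   `age_years` and the rate column; rows flagged in an `excluded` column
#'   are dropped first.
#' @param rate_col Name of the rate column (default `"rate_c_mean"`, the
#'   carbon-normalized replicate mean; a bare `"rate"` column is also
#'   accepted).
#' @param n_starts Number of jittered restarts per core.
#' @param scale `"log"` (default) or `"linear"`: the scale on which
#'   least-squares residuals are taken.
#' @return An object of class `ch4_decay_fit` with [coef()], [print()],
#'   [summary()], [predict()], [fitted()], [residuals()] and [plot()]
#'   methods, and per-core standard errors for interval work.
#' @seealso [transition_age()], [integrate_lifetime()]
#' @export
fit_decay <- function(data, rate_col = "rate_c_mean", n_starts = 10,
                      scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!rate_col %in% names(data) && "rate" %in% names(data)) {
    rate_col <- "rate"
  }
  stopifnot(all(c("core_id", "age_years", rate_col) %in% names(data)))
  if ("excluded" %in% names(data)) data <- data[!data$excluded, ]
  data <- data[is.finite(data[[rate_col]]) & is.finite(data$age_years), ]
  if (scale == "log") {
    npos <- sum(data[[rate_col]] <= 0)
    if (npos > 0) {
      message(npos, " non-positive net rates dropped from log-scale decay fit")
      data <- data[data[[rate_col]] > 0, ]
    }
  }
  fits <- list()
  for (core in unique(data$core_id)) {
    d <- data[data$core_id == core, ]
    if (length(unique(d$age_years)) < 3) {
      fits[[core]] <- list(coef = c(a = NA_real_, b = NA_real_, c = NA_real_),
                           se = c(a = NA_real_, b = NA_real_, c = NA_real_),
                           rss = NA_real_, sigma2 = NA_real_, n = nrow(d),
                           converged = FALSE, boundary = FALSE)
      next
    }
    fits[[core]] <- fit_decay_one(d$age_years, d[[rate_col]],
                                  n_starts = n_starts, scale = scale)
  }
  structure(list(fits = fits, data = data, rate_col = rate_col,
                 scale = scale, call = match.call()),
            class = "ch4_decay_fit")
}

#' @export
coef.ch4_decay_fit <- function(object, ...) {
  t(vapply(object$fits, function(f) f$coef, numeric(3)))
}

#' @export
print.ch4_decay_fit <- function(x, digits = 4, ...) {
  cat("Per-core exponential decay fits: rate = a*exp(-b*age) + c\n")
  cat(sprintf("%d cores, %d observations\n\n", length(x$fits), nrow(x$data)))
  print(round(summary(x)[, c("a", "b", "c", "rss", "n", "converged")],
              digits))
  invisible(x)
}

#' @export
summary.ch4_decay_fit <- function(object, ...) {
  rows <- lapply(names(object$fits), function(core) {
    f <- object$fits[[core]]
    data.frame(core_id = core, a = f$coef["a"], b = f$coef["b"],
               c = f$coef["c"], se_a = f$se["a"], se_b = f$se["b"],
               se_c = f$se["c"], rss = f$rss, sigma2 = f$sigma2, n = f$n,
               converged = f$converged, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' @export
predict.ch4_decay_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  stopifnot(all(c("core_id", "age_years") %in% names(newdata)))
  out <- rep(NA_real_, nrow(newdata))
  for (core in unique(newdata$core_id)) {
    f <- object$fits[[core]]
    if (is.null(f)) next
    idx <- newdata$core_id == core
    out[idx] <- decay_curve(f$coef["a"], f$coef["b"], f$coef["c"],
                            newdata$age_years[idx])
  }
  out
}

#' @export
fitted.ch4_decay_fit <- function(object, ...) predict(object)

#' @export
residuals.ch4_decay_fit <- function(object, ...) {
  object$data[[object$rate_col]] - predict(object)
}

#' @export
plot.ch4_decay_fit <- function(x, cores = NULL, ...) {
  cores <- if (is.null(cores)) names(x$fits) else cores
  nc <- ceiling(sqrt(length(cores)))
  op <- graphics::par(mfrow = c(ceiling(length(cores) / nc), nc),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (core in cores) {
    d <- x$data[x$data$core_id == core, ]
    f <- x$fits[[core]]
    graphics::plot(d$age_years, d[[x$rate_col]], xlab = "Sediment age (y)",
                   ylab = expression(CH[4] ~ (mu * mol ~ gC^-1 ~ d^-1)),
                   main = core, ...)
    if (all(is.finite(f$coef))) {
      ag <- seq(min(d$age_years), max(d$age_years), length.out = 200)
      graphics::lines(ag, decay_curve(f$coef["a"], f$coef["b"], f$coef["c"],
                                      ag))
    }
  }
  invisible(x)
}

#' Transition age to low background CH4 formation
#'
#' The transition age is the sediment age at which the fitted decay curve
#' becomes effectively flat: where the tangent of the modelled curve (rate in
#' µmol gC^-1 d^-1 against age in years) reaches an angle of
#' `criterion_angle` degrees, i.e. `|d rate / d age| = tan(180 -
#' criterion_angle)`. For the decay curve this has the closed form
#' `t* = ln(a b / tan(theta)) / b` with `theta = (180 - criterion_angle)` in
#' radians, and `t* = 0` when the curve is already flatter than the
#' criterion at age zero (`a b <= tan(theta)`). The constant pool `c` does
#' not enter. The criterion is scale-dependent by construction; the unit
#' convention above is part of its definition.
#'
#' @param object A `ch4_decay_fit`, or a numeric `a` (with `b` supplied) for
#'   the closed form directly.
#' @param ... Passed between methods.
#' @return For fits, a `data.frame` (`core_id`, `a`, `b`, `c`,
#'   `transition_age_y`, `converged`); for numerics, the transition age in
#'   years.
#' @examples
#' transition_age(10, b = 0.3)  # ~17.16 y
#' @export
transition_age <- function(object, ...) UseMethod("transition_age")

#' @rdname transition_age
#' @param b Decay rate (per year), > 0.
#' @param criterion_angle Flatness criterion in degrees (default 179).
#' @export
transition_age.default <- function(object, b, criterion_angle = 179, ...) {
  a <- object
  if (any(b <= 0)) stop("b must be positive", call. = FALSE)
  if (any(a < 0)) stop("a must be non-negative", call. = FALSE)
  thr <- tan((180 - criterion_angle) * pi / 180)
  ifelse(a * b <= thr, 0, log(a * b / thr) / b)
}

#' @rdname transition_age
#' @export
transition_age.ch4_decay_fit <- function(object, criterion_angle = 179, ...) {
  s <- summary(object)
  s$transition_age_y <- NA_real_
  ok <- s$converged & is.finite(s$a) & is.finite(s$b)
  s$transition_age_y[ok] <- transition_age(s$a[ok], b = s$b[ok],
                                           criterion_angle = criterion_angle)
  s[, c("core_id", "a", "b", "c", "transition_age_y", "converged")]
}

#' Sediment depth corresponding to a transition age
#'
#' Inverts the age-depth map (with no incubation term): a sediment age maps
#' to the depth `(t* / reservoir_age) * total_depth`. Ages beyond the
#' reservoir age are capped at the total sediment depth with a warning.
#'
#' @param t_star_y Transition age(s) in years, >= 0.
#' @param total_depth_cm Total sediment depth (cm).
#' @param reservoir_age_y Reservoir age at sampling (years).
#' @return Depth in cm (vectorized).
#' @export
transition_depth <- function(t_star_y, total_depth_cm, reservoir_age_y) {
  if (any(t_star_y < 0)) stop("t_star_y must be >= 0", call. = FALSE)
  if (any(reservoir_age_y <= 0) || any(total_depth_cm <= 0)) {
    stop("geometry must be positive", call. = FALSE)
  }
  over <- t_star_y > reservoir_age_y
  if (any(over)) {
    warning("transition age exceeds reservoir age; depth capped at total depth")
  }
  pmin(t_star_y / reservoir_age_y, 1) * total_depth_cm
}

#' Pearson correlation of transition age with surface-sediment C:N
#'
#' Tests whether cores receiving more terrestrial (high C:N) organic matter
#' transition to background CH4 formation later, via a Pearson correlation
#' and the least-squares slope of transition age on surface C:N.
#'
#' @param transition_age_y Per-core transition ages (years).
#' @param cn Per-core surface-sediment C:N (mass ratio).
#' @return List with `slope`, `intercept`, `r`, `r2`, `p`, `n`.
#' @export
transition_vs_cn <- function(transition_age_y, cn) {
  ok <- is.finite(transition_age_y) & is.finite(cn)
  t <- transition_age_y[ok]; x <- cn[ok]
  if (length(t) < 3) stop("need at least 3 cores", call. = FALSE)
  if (stats::var(t) == 0 || stats::var(x) == 0) {
    stop("zero variance in transition age or C:N", call. = FALSE)
  }
  ct <- stats::cor.test(x, t, method = "pearson")
  co <- stats::coef(stats::lm(t ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(t))
}
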