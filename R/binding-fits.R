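# Elementary kinetic and thermodynamic fits on bound-fraction data:
# single-exponential association and dissociation, kobs-vs-[E] regression
# for kon, quadratic tight-binding titration for Kd, and single-turnover
# activity fits.

#' Time-resolved bound-fraction series
#'
#' Container for a bound-fraction time course p(t) with its concentration
#' context. Noise can push individual p values slightly outside `[0, 1]`;
#' such values are retained unclipped and the fitters tolerate them.
#'
#' @param times nonnegative, strictly increasing times (s); >= 5 points.
#' @param p bound fractions.
#' @param CE enzyme concentration (M).
#' @param CS labelled RNA concentration (M).
#' @param kind one of `"association"`, `"dissociation"`, `"activity"`.
#' @return object of class `bound_fraction_series`.
#' @export
bound_fraction_series <- function(times, p, CE = NA_real_, CS = NA_real_,
                                  kind = c("association", "dissociation",
                                           "activity")) {
  kind <- match.arg(kind)
  check_times(times)
  if (length(times) < 5L) stop("need at least 5 points", call. = FALSE)
  if (length(p) != length(times) || anyNA(p)) {
    stop("'p' must match 'times' and contain no NA", call. = FALSE)
  }
  structure(list(times = times, p = p, CE = CE, CS = CS, kind = kind),
            class = "bound_fraction_series")
}

#' @export
print.bound_fraction_series <- function(x, ...) {
  cat(sprintf("%s series: %d points over %.4g s (CE = %.3g M, CS = %.3g M)\n",
              x$kind, length(x$times), max(x$times), x$CE, x$CS))
  invisible(x)
}

#' Fit a single-exponential association time course
#'
#' Fits `p(t) = p_eq (1 - exp(-kobs t))` (optionally with a fixed nonzero
#' starting bound fraction `p(0) = baseline`, default 0 since mixing starts
#' unbound) to derive the apparent pseudo-first-order binding rate `kobs`.
#'
#' @param series a [bound_fraction_series()] of kind `"association"`.
#' @param baseline fixed bound fraction at t = 0.
#' @return object of classes `assoc_fit`/`kinfit`; `coef()` gives `kobs`
#'   (s^-1) and `p_eq`.
#' @export
fit_association <- function(series, baseline = 0) {
  stopifnot(inherits(series, "bound_fraction_series"))
  if (series$kind != "association") {
    stop("series kind must be 'association'", call. = FALSE)
  }
  tt <- series$times; y <- series$p
  n <- length(tt)
  if (stats::cor(tt, y, method = "spearman") < -0.3 && y[n] < y[1L]) {
    stop(paste("series decreases over time; this looks like a dissociation",
               "curve (kind mismatch?)"), call. = FALSE)
  }
  model_fn <- function(par, t) {
    par[["p_eq"]] + (baseline - par[["p_eq"]]) * exp(-par[["kobs"]] * t)
  }
  resid_fn <- function(par) model_fn(par, tt) - y
  # init: amplitude from the plateau; rate from a log-linear regression of
  # the unrelaxed fraction over the early part of the curve
  p_eq0 <- max(stats::median(utils::tail(y, max(3L, n %/% 3L))), 1e-3)
  frac <- 1 - y / (1.05 * max(p_eq0, max(y)))
  early <- which(frac > 0.02)
  early <- early[early <= ceiling(2 * n / 3)]
  k0 <- if (length(early) >= 2) {
    max(-stats::coef(stats::lm(log(frac[early]) ~ tt[early]))[[2L]], 1e-6)
  } else 1 / max(tt[2L], 1e-6)
  starts <- lapply(c(0.25, 1, 4), function(f) {
    c(kobs = as.numeric(k0 * f), p_eq = p_eq0)
  })
  best <- nls_multistart(resid_fn, starts,
                         lower = c(kobs = 1e-12, p_eq = 0),
                         upper = c(kobs = Inf, p_eq = 1.2))
  est <- unlist(best$fit$par)
  new_kinfit("assoc_fit", est, lm_std_errors(best$fit),
             data = list(x = tt, y = y), model_fn = model_fn, best = best,
             fixed = list(baseline = baseline, CE = series$CE,
                          CS = series$CS),
             extra = list(xlab = "time (s)", ylab = "bound fraction"),
             label = sprintf("association fit (CE = %.3g M)", series$CE))
}

#' Association rate from the concentration dependence of kobs
#'
#' Weighted linear regression `kobs = kon [E] + koff`. The slope is the
#' association rate `kon`; the intercept is reported but flagged
#' low-confidence, since an off-rate is poorly determined from extrapolation
#' to zero enzyme and should be measured by a dissociation experiment.
#'
#' @param CE enzyme concentrations (M), >= 3 distinct values.
#' @param kobs apparent binding rates (s^-1).
#' @param sd optional per-point standard deviations of `kobs`; when present
#'   the regression is weighted by `1/sd^2`.
#' @return list of class `kobs_line` with `kon`, `kon_se`, `intercept`,
#'   `intercept_se`, `intercept_reliable = FALSE` and the underlying `lm`.
#' @export
fit_kobs_line <- function(CE, kobs, sd = NULL) {
  if (length(unique(CE)) < 3L) {
    stop("need kobs at >= 3 distinct enzyme concentrations", call. = FALSE)
  }
  if (length(kobs) != length(CE)) stop("length mismatch", call. = FALSE)
  w <- if (is.null(sd)) NULL else 1 / sd^2
  fit <- stats::lm(kobs ~ CE, weights = w)
  sm <- summary(fit)$coefficients
  structure(list(kon = sm["CE", "Estimate"], kon_se = sm["CE", "Std. Error"],
                 intercept = sm["(Intercept)", "Estimate"],
                 intercept_se = sm["(Intercept)", "Std. Error"],
                 intercept_reliable = FALSE, lm = fit,
                 data = data.frame(CE = CE, kobs = kobs)),
            class = "kobs_line")
}

#' @export
print.kobs_line <- function(x, ...) {
  cat(sprintf("kobs vs [E]: kon = %.4g +/- %.2g M^-1 s^-1\n", x$kon,
              x$kon_se))
  cat(sprintf("  intercept = %.4g +/- %.2g s^-1 (low confidence;\n",
              x$intercept, x$intercept_se))
  cat("  measure koff by a dissociation experiment instead)\n")
  invisible(x)
}

#' @export
coef.kobs_line <- function(object, ...) {
  c(kon = object$kon, intercept = object$intercept)
}

#' Fit a single-exponential dissociation time course
#'
#' Fits `p(t) = p0 exp(-koff t)` to a post-dilution chase. Also returns the
#' normalised curve `p(t)/p0` conventionally used for display.
#'
#' @param series a [bound_fraction_series()] of kind `"dissociation"`.
#' @return object of classes `dissoc_fit`/`kinfit`; `coef()` gives `koff`
#'   (s^-1) and `p0`; `$normalized` holds `p(t)/p0`.
#' @export
fit_dissociation <- function(series) {
  stopifnot(inherits(series, "bound_fraction_series"))
  if (series$kind != "dissociation") {
    stop("series kind must be 'dissociation'", call. = FALSE)
  }
  tt <- series$times; y <- series$p
  model_fn <- function(par, t) par[["p0"]] * exp(-par[["koff"]] * t)
  resid_fn <- function(par) model_fn(par, tt) - y
  pos <- which(y > 0)
  k0 <- if (length(pos) >= 3) {
    max(-stats::coef(stats::lm(log(y[pos]) ~ tt[pos]))[[2L]], 1e-8)
  } else 1 / max(tt)
  p00 <- max(y[1L], 1e-3)
  starts <- lapply(c(0.25, 1, 4), function(f) {
    c(koff = as.numeric(k0 * f), p0 = p00)
  })
  best <- nls_multistart(resid_fn, starts,
                         lower = c(koff = 1e-12, p0 = 0),
                         upper = c(koff = Inf, p0 = 1.2))
  est <- unlist(best$fit$par)
  out <- new_kinfit("dissoc_fit", est, lm_std_errors(best$fit),
                    data = list(x = tt, y = y), model_fn = model_fn,
                    best = best,
                    fixed = list(CE = series$CE, CS = series$CS),
                    extra = list(xlab = "time (s)",
                                 ylab = "bound fraction"),
                    label = "single-exponential dissociation fit")
  out$normalized <- data.frame(time_s = tt, p_norm = y / est[["p0"]])
  out
}

#' Fit an equilibrium titration with the quadratic tight-binding isotherm
#'
#' One-parameter least-squares fit of [equilibrium_occupancy()] to a
#' titration of labelled RNA with enzyme, yielding the apparent equilibrium
#' dissociation constant Kd. The exact quadratic isotherm is used because
#' the RNA concentration is not always negligible against Kd. Optionally a
#' free amplitude absorbs incomplete-binding artifacts (off by default:
#' binding saturates at 1).
#'
#' @param CE enzyme concentrations (M), >= 6 values spanning the expected Kd.
#' @param p bound fractions at each `CE`.
#' @param CS total labelled RNA concentration (M).
#' @param amplitude fit a free saturation amplitude? Default `FALSE`.
#' @return object of classes `titration_fit`/`kinfit`; `coef()` gives `Kd`
#'   (M) and, when fitted, `amplitude`. `$local_min_ok` records an on-run
#'   sanity check that SSR at the fitted Kd is below SSR at 2 Kd and Kd/2.
#' @export
fit_titration <- function(CE, p, CS, amplitude = FALSE) {
  if (length(CE) < 6L) {
    stop("need >= 6 enzyme concentrations", call. = FALSE)
  }
  if (length(p) != length(CE)) stop("length mismatch", call. = FALSE)
  if (all(p < 0.1) || all(p > 0.9)) {
    stop(paste("titration is unidentifiable: all bound fractions are near 0",
               "or near 1; extend the concentration range across the",
               "expected Kd"), call. = FALSE)
  }
  stop_if_not_scalar_nonneg(CS, "CS")
  model_fn <- if (amplitude) {
    function(par, ce) par[["amplitude"]] * equilibrium_occupancy(CS, ce, par[["Kd"]])
  } else {
    function(par, ce) equilibrium_occupancy(CS, ce, par[["Kd"]])
  }
  resid_fn <- function(par) model_fn(par, CE) - p
  # init Kd at the (interpolated) concentration where p crosses half-saturation
  ord <- order(CE)
  half <- 0.5 * max(p)
  Kd0 <- tryCatch(stats::approx(p[ord], CE[ord], xout = half,
                                ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- exp(mean(log(range(CE[CE > 0]))))
  starts <- lapply(c(0.1, 1, 10), function(f) {
    if (amplitude) c(Kd = Kd0 * f, amplitude = max(p)) else c(Kd = Kd0 * f)
  })
  lower <- if (amplitude) c(Kd = 1e-15, amplitude = 0.05) else c(Kd = 1e-15)
  upper <- if (amplitude) c(Kd = Inf, amplitude = 1.5) else c(Kd = Inf)
  best <- nls_multistart(resid_fn, starts, lower = lower, upper = upper)
  est <- unlist(best$fit$par)
  out <- new_kinfit("titration_fit", est, lm_std_errors(best$fit),
                    data = list(x = CE, y = p), model_fn = model_fn,
                    best = best, fixed = list(CS = CS),
                    extra = list(log_x = TRUE, xlab = "[E] (M)",
                                 ylab = "bound fraction"),
                    label = "quadratic tight-binding titration fit")
  ssr_at <- function(kd) {
    pp <- est; pp[["Kd"]] <- kd
    sum((model_fn(pp, CE) - p)^2)
  }
  out$local_min_ok <- out$ssr <= ssr_at(2 * est[["Kd"]]) + 1e-15 &&
    out$ssr <= ssr_at(est[["Kd"]] / 2) + 1e-15
  out
}

#' Fit a single-turnover activity time course
#'
#' Fits the product fraction to `f(t) = 1 - exp(-k t)` and reports the
#' apparent single-turnover rate (which conflates substrate loading and
#' chemistry) together with the half-time `ln 2 / k`.
#'
#' @param times reaction times (s).
#' @param f product fractions in `[0, 1]` (up to noise), increasing trend.
#' @return object of classes `turnover_fit`/`kinfit`; `coef()` gives `k`
#'   (s^-1); `$t_half_s` and `$t_half_min` give the half-time.
#' @export
fit_single_turnover <- function(times, f) {
  check_times(times)
  if (length(f) != length(times)) stop("length mismatch", call. = FALSE)
  model_fn <- function(par, t) 1 - exp(-par[["k"]] * t)
  resid_fn <- function(par) model_fn(par, times) - f
  frac <- pmax(1 - f, 1e-10)
  k0 <- max(-stats::coef(stats::lm(log(frac) ~ times))[[2L]], 1e-8)
  starts <- lapply(c(0.25, 1, 4), function(g) c(k = as.numeric(k0 * g)))
  best <- nls_multistart(resid_fn, starts, lower = c(k = 1e-12))
  est <- unlist(best$fit$par)
  out <- new_kinfit("turnover_fit", est, lm_std_errors(best$fit),
                    data = list(x = times, y = f), model_fn = model_fn,
                    best = best,
                    extra = list(xlab = "time (s)",
                                 ylab = "product fraction"),
                    label = "single-turnover activity fit")
  out$t_half_s <- log(2) / est[["k"]]
  out$t_half_min <- out$t_half_s / 60
  out
}

#' Fold change between two positive quantities
#'
#' Ratio `a/b` with the reporting conventions used for rate and affinity
#' comparisons: ratios of about 10 and above are quoted to the nearest
#' integer, smaller ones to one decimal.
#'
#' @param a,b positive scalars.
#' @param rounding `"none"`, `"integer"`, or `"one_decimal"`.
#' @return the (optionally rounded) ratio `a/b`.
#' @examples
#' fold_change(0.9, 0.031, "integer")   # 29
#' fold_change(12, 5, "one_decimal")    # 2.4
#' @export
fold_change <- function(a, b, rounding = c("none", "integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0) {
    stop("both inputs must be positive", call. = FALSE)
  }
  r <- a / b
  switch(rounding, none = r, integer = round(r), one_decimal = round(r, 1))
}
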