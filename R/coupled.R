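# Coupled dissociation-catalysis-release analysis: dilution chases of a
# slowly reacting enzyme-substrate complex collected after several
# incubation times are fit globally to a double exponential with shared
# rates; the amplitude decay across incubation times yields the on-enzyme
# modification rate kcat, and the shared rates disentangle into the product
# and substrate off-rates.

#' Bundle of dilution chases collected after different incubation times
#'
#' @param series list of [bound_fraction_series()] (kind `"dissociation"`),
#'   one per incubation time, each with >= 8 points.
#' @param T_inc incubation times (s), distinct, same length as `series`.
#' @param CS,CE pre-dilution concentrations (M).
#' @param dilution_factor dilution applied at t = 0 (default 4000).
#' @return object of class `coupled_experiment`.
#' @export
coupled_experiment <- function(series, T_inc, CS, CE,
                               dilution_factor = 4000) {
  if (!is.list(series) || length(series) < 2L) {
    stop("need series for at least 2 incubation times", call. = FALSE)
  }
  if (length(T_inc) != length(series)) stop("length mismatch", call. = FALSE)
  if (anyDuplicated(T_inc)) {
    stop("incubation times must be distinct", call. = FALSE)
  }
  for (i in seq_along(series)) {
    s <- series[[i]]
    if (!inherits(s, "bound_fraction_series")) {
      stop("each element must be a bound_fraction_series", call. = FALSE)
    }
    if (length(s$times) < 8L) {
      stop(sprintf("series %d has fewer than 8 points", i), call. = FALSE)
    }
  }
  ord <- order(T_inc)
  structure(list(series = series[ord], T_inc = as.numeric(T_inc[ord]),
                 CS = CS, CE = CE, dilution_factor = dilution_factor),
            class = "coupled_experiment")
}

#' @export
print.coupled_experiment <- function(x, ...) {
  cat(sprintf(paste0("coupled dissociation experiment: %d incubation times",
                     " (%s min),\n  CS = %.3g M, CE = %.3g M, %g-fold",
                     " dilution\n"),
              length(x$T_inc), paste(round(x$T_inc / 60), collapse = ", "),
              x$CS, x$CE, x$dilution_factor))
  invisible(x)
}

# deterministic multistart grid for the global double-exponential fit
coupled_starts <- function(exp, n_starts = 8) {
  p1 <- vapply(exp$series, function(s) max(min(s$p[1L], 1.2), 0.01),
               numeric(1))
  # pooled single-exponential rate as an anchor
  k_pool <- stats::median(vapply(exp$series, function(s) {
    pos <- which(s$p > 0)
    if (length(pos) >= 3) {
      max(-stats::coef(stats::lm(log(s$p[pos]) ~ s$times[pos]))[[2L]], 1e-8)
    } else 1 / max(s$times)
  }, numeric(1)))
  grid <- expand.grid(ratio = c(5, 14, 40), k2f = c(0.5, 1), f1 = c(0.3, 0.7))
  grid <- grid[seq_len(min(n_starts - 1L, nrow(grid))), ]
  starts <- lapply(seq_len(nrow(grid)), function(i) {
    k2 <- k_pool * grid$k2f[i]
    c(logk1 = log(k2 * grid$ratio[i]), logk2 = log(k2),
      stats::setNames(grid$f1[i] * p1, paste0("A1_", seq_along(p1))),
      stats::setNames((1 - grid$f1[i]) * p1, paste0("A2_", seq_along(p1))))
  })
  # a start on the single-exponential manifold (A1 ~ 0)
  starts[[length(starts) + 1L]] <-
    c(logk1 = log(10 * k_pool), logk2 = log(k_pool),
      stats::setNames(rep(0.01, length(p1)), paste0("A1_", seq_along(p1))),
      stats::setNames(p1, paste0("A2_", seq_along(p1))))
  starts
}

#' Global double-exponential fit across incubation times
#'
#' Simultaneous least squares over all chases:
#' `p_i(t) = A1_i exp(-k1 t) + A2_i exp(-k2 t)`, with the two decay rates
#' shared by every curve and the amplitudes free per curve. Rates are
#' optimised on the log scale (positive by construction) by multistart
#' Levenberg-Marquardt; amplitudes are bounded to `[0, 1.2]` to absorb
#' noise overshoot. The label tie-break makes `k1` the faster rate. A
#' converged rate ratio `k1/k2 < 3` triggers an identifiability warning;
#' rate collapse (`k1 ~ k2`) triggers a degenerate-fit warning and attaches
#' a global single-exponential fallback.
#'
#' @param exp a [coupled_experiment()].
#' @param n_starts number of multistart initialisations (default 8).
#' @return object of class `coupled_fit` with elements `k1`, `k2` (s^-1,
#'   with `k1_se`, `k2_se`), `amplitudes` (data frame: `T_s`, `A1`, `A2`
#'   and their SEs), `ssr`, `residuals` (list per curve), `converged`,
#'   `degenerate`, and `single_fallback` when degenerate.
#' @export
global_double_exp_fit <- function(exp, n_starts = 8) {
  stopifnot(inherits(exp, "coupled_experiment"))
  nc <- length(exp$series)
  times <- lapply(exp$series, `[[`, "times")
  ys <- lapply(exp$series, `[[`, "p")
  resid_fn <- function(par) {
    k1 <- exp(par[["logk1"]]); k2 <- exp(par[["logk2"]])
    unlist(lapply(seq_len(nc), function(i) {
      par[[paste0("A1_", i)]] * exp(-k1 * times[[i]]) +
        par[[paste0("A2_", i)]] * exp(-k2 * times[[i]]) - ys[[i]]
    }))
  }
  npar <- 2L + 2L * nc
  lower <- c(logk1 = -Inf, logk2 = -Inf, rep(0, 2L * nc))
  upper <- c(logk1 = Inf, logk2 = Inf, rep(1.2, 2L * nc))
  best <- nls_multistart(resid_fn, coupled_starts(exp, n_starts),
                         lower = lower, upper = upper)
  par <- unlist(best$fit$par)
  se <- lm_std_errors(best$fit)
  k1 <- exp(par[["logk1"]]); k2 <- exp(par[["logk2"]])
  k1_se <- k1 * se[["logk1"]]; k2_se <- k2 * se[["logk2"]]
  A1 <- par[paste0("A1_", seq_len(nc))]
  A2 <- par[paste0("A2_", seq_len(nc))]
  A1_se <- se[paste0("A1_", seq_len(nc))]
  A2_se <- se[paste0("A2_", seq_len(nc))]
  if (k1 < k2) {  # tie-break: k1 is the faster rate
    tmp <- k1; k1 <- k2; k2 <- tmp
    tmp <- k1_se; k1_se <- k2_se; k2_se <- tmp
    tmp <- A1; A1 <- A2; A2 <- tmp
    tmp <- A1_se; A1_se <- A2_se; A2_se <- tmp
  }
  degenerate <- abs(k1 - k2) < 1e-9 * k1 || k1 / k2 < 1.05
  single_fallback <- NULL
  if (degenerate) {
    warning(paste("rate collapse (k1 ~ k2): double-exponential model is",
                  "degenerate; single-exponential fallback attached"))
    single_fallback <- lapply(exp$series, fit_dissociation)
  } else if (k1 / k2 < 3) {
    warning(sprintf(
      "fitted rate ratio k1/k2 = %.2f < 3: the two components are poorly separated",
      k1 / k2))
  }
  fitted <- lapply(seq_len(nc), function(i) {
    A1[i] * exp(-k1 * times[[i]]) + A2[i] * exp(-k2 * times[[i]])
  })
  structure(list(
    k1 = k1, k2 = k2, k1_se = k1_se, k2_se = k2_se,
    amplitudes = data.frame(T_s = exp$T_inc, A1 = unname(A1),
                            A1_se = unname(A1_se), A2 = unname(A2),
                            A2_se = unname(A2_se)),
    ssr = best$ssr_trace[which.min(best$ssr_trace)],
    residuals = lapply(seq_len(nc), function(i) ys[[i]] - fitted[[i]]),
    fitted = fitted, times = times, observed = ys,
    n_points = sum(lengths(times)), n_par = npar,
    converged = best$converged, iterations = best$niter,
    degenerate = degenerate, single_fallback = single_fallback,
    experiment = exp), class = "coupled_fit")
}

#' @export
print.coupled_fit <- function(x, ...) {
  cat("Global double-exponential dissociation fit\n")
  cat(sprintf("  k1 (fast) = %.4g +/- %.2g s^-1\n", x$k1, x$k1_se))
  cat(sprintf("  k2 (slow) = %.4g +/- %.2g s^-1  (ratio %.1f)\n",
              x$k2, x$k2_se, x$k1 / x$k2))
  cat(sprintf("  %d curves, %d points, SSR %.4g\n",
              nrow(x$amplitudes), x$n_points, x$ssr))
  print(x$amplitudes, digits = 3)
  invisible(x)
}

#' @export
coef.coupled_fit <- function(object, ...) {
  c(k1 = object$k1, k2 = object$k2)
}

#' @export
residuals.coupled_fit <- function(object, ...) object$residuals

#' @export
plot.coupled_fit <- function(x, ...) {
  cols <- grDevices::hcl.colors(length(x$times), "Dark 3")
  graphics::plot(NA, xlim = range(unlist(x$times)),
                 ylim = range(c(0, unlist(x$observed))),
                 xlab = "time after dilution (s)", ylab = "bound fraction",
                 ...)
  for (i in seq_along(x$times)) {
    graphics::points(x$times[[i]], x$observed[[i]], col = cols[i], pch = 16,
                     cex = 0.5)
    graphics::lines(x$times[[i]], x$fitted[[i]], col = cols[i])
  }
  graphics::legend("topright", bty = "n", col = cols, lty = 1,
                   legend = sprintf("T = %g min", x$amplitudes$T_s / 60))
  invisible(x)
}

#' Single-exponential fit of amplitude decay across incubation times
#'
#' The amplitude of the slow component decays as `A2(T) = b exp(-kcat T)`
#' (unmodified substrate remaining), while the fast-component amplitude
#' grows toward saturation as `A1(T) = a (1 - exp(-kcat T))` (product
#' accumulated); each form yields an independent kcat estimate.
#'
#' @param T_inc incubation times (s), >= 3 values.
#' @param A amplitudes at each `T_inc`.
#' @param form `"decay"` for the slow/substrate component, `"rise"` for the
#'   fast/product component.
#' @return object of classes `amplitude_fit`/`kinfit`; `coef()` gives
#'   `kcat` (s^-1) and the scale parameter.
#' @export
fit_amplitude_decay <- function(T_inc, A, form = c("decay", "rise")) {
  form <- match.arg(form)
  if (length(T_inc) < 3L) stop("need >= 3 incubation times", call. = FALSE)
  if (length(A) != length(T_inc)) stop("length mismatch", call. = FALSE)
  rho <- suppressWarnings(stats::cor(T_inc, A, method = "spearman"))
  if (is.finite(rho) &&
      ((form == "decay" && rho > 0.3) || (form == "rise" && rho < -0.3))) {
    warning(sprintf("amplitudes trend the wrong way for form = '%s'", form))
  }
  model_fn <- if (form == "decay") {
    function(par, T_) par[["scale"]] * exp(-par[["kcat"]] * T_)
  } else {
    function(par, T_) par[["scale"]] * (1 - exp(-par[["kcat"]] * T_))
  }
  resid_fn <- function(par) model_fn(par, T_inc) - A
  sc0 <- max(max(abs(A)), 1e-3)
  k0 <- 1 / max(stats::median(T_inc), 1e-6)
  starts <- lapply(c(0.2, 1, 5), function(f) {
    c(kcat = k0 * f, scale = sc0)
  })
  best <- nls_multistart(resid_fn, starts,
                         lower = c(kcat = 1e-12, scale = 1e-6),
                         upper = c(kcat = Inf, scale = 1.5))
  est <- unlist(best$fit$par)
  new_kinfit("amplitude_fit", est, lm_std_errors(best$fit),
             data = list(x = T_inc, y = A), model_fn = model_fn, best = best,
             fixed = list(form = form),
             extra = list(xlab = "incubation time (s)", ylab = "amplitude"),
             label = sprintf("amplitude %s fit", form))
}

#' kcat from both amplitude series of a global fit
#'
#' Fits `A2(T)` (decay) and `A1(T)` (rise) and reports the mean and
#' standard deviation of the two kcat estimates.
#'
#' @param fit a `coupled_fit` from [global_double_exp_fit()].
#' @return list with `kcat` (mean), `kcat_sd`, `kcat_A1`, `kcat_A2` and
#'   the underlying fits.
#' @export
kcat_from_amplitudes <- function(fit) {
  stopifnot(inherits(fit, "coupled_fit"))
  amp <- fit$amplitudes
  f1 <- fit_amplitude_decay(amp$T_s, amp$A1, form = "rise")
  f2 <- fit_amplitude_decay(amp$T_s, amp$A2, form = "decay")
  ks <- c(coef(f1)[["kcat"]], coef(f2)[["kcat"]])
  list(kcat = mean(ks), kcat_sd = stats::sd(ks),
       kcat_A1 = ks[1L], kcat_A2 = ks[2L], fit_A1 = f1, fit_A2 = f2)
}

#' Nested comparison of single- versus double-exponential decay
#'
#' Fits both models to one dissociation curve and compares them with an
#' extra-sum-of-squares F test (single nested in double at `A1 = 0`):
#' `F = ((SSR1 - SSR2)/2) / (SSR2/(n - 4))`. The double fit is seeded from
#' the single-exponential solution, so `SSR_double <= SSR_single` by
#' construction.
#'
#' @param series a [bound_fraction_series()] with >= 10 points.
#' @param alpha significance level for the preference call (default 0.05).
#' @return list of class `exp_model_comparison`: `single`, `double` (fits),
#'   `ssr_single`, `ssr_double`, `F`, `p_value`, `prefer`
#'   (`"single"`/`"double"`), residual series for both models.
#' @export
compare_exponential_models <- function(series, alpha = 0.05) {
  stopifnot(inherits(series, "bound_fraction_series"))
  tt <- series$times; y <- series$p
  n <- length(tt)
  if (n < 10L) stop("need >= 10 points", call. = FALSE)
  single <- fit_dissociation(series)
  k_s <- coef(single)[["koff"]]; p0_s <- coef(single)[["p0"]]
  model_fn <- function(par, t) {
    par[["A1"]] * exp(-exp(par[["logk1"]]) * t) +
      par[["A2"]] * exp(-exp(par[["logk2"]]) * t)
  }
  resid_fn <- function(par) model_fn(par, tt) - y
  starts <- list(
    c(logk1 = log(10 * k_s), logk2 = log(k_s), A1 = 0, A2 = p0_s),
    c(logk1 = log(5 * k_s), logk2 = log(k_s / 2), A1 = 0.3 * p0_s,
      A2 = 0.7 * p0_s),
    c(logk1 = log(20 * k_s), logk2 = log(k_s), A1 = 0.5 * p0_s,
      A2 = 0.5 * p0_s),
    c(logk1 = log(2 * k_s), logk2 = log(k_s / 5), A1 = 0.7 * p0_s,
      A2 = 0.3 * p0_s))
  best <- nls_multistart(resid_fn, starts,
                         lower = c(logk1 = -Inf, logk2 = -Inf, A1 = 0, A2 = 0),
                         upper = c(logk1 = Inf, logk2 = Inf, A1 = 1.2,
                                   A2 = 1.2))
  par <- unlist(best$fit$par)
  ssr1 <- single$ssr
  fitted2 <- model_fn(par, tt)
  ssr2 <- min(sum((fitted2 - y)^2), ssr1)
  df2 <- n - 4L
  Fstat <- ((ssr1 - ssr2) / 2) / (ssr2 / df2)
  p_value <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  structure(list(single = single, double_par = par,
                 ssr_single = ssr1, ssr_double = ssr2,
                 F = Fstat, p_value = p_value,
                 prefer = if (p_value < alpha) "double" else "single",
                 residuals_single = residuals(single),
                 residuals_double = y - fitted2,
                 alpha = alpha, n = n), class = "exp_model_comparison")
}

#' @export
print.exp_model_comparison <- function(x, ...) {
  cat(sprintf(paste0("single vs double exponential: SSR %.4g vs %.4g,\n",
                     "  F(2, %d) = %.3g, p = %.3g -> prefer %s model\n"),
              x$ssr_single, x$ssr_double, x$n - 4L, x$F, x$p_value,
              x$prefer))
  invisible(x)
}

#' Disentangle off-rates from the shared decay rates and kcat
#'
#' Under the coupled scheme the fast global decay rate is the product
#' off-rate (`koff_P = k1`) and the slow rate is the sum of modification
#' and substrate dissociation (`k2 = kcat + koff_S`). Uncertainties combine
#' in quadrature. When `kcat / (k1 - k2)` exceeds 0.2 the two-exponential
#' reading is unreliable (conversion flux during the chase is no longer
#' negligible) and a warning is emitted.
#'
#' @param fit a `coupled_fit`.
#' @param kcat on-enzyme modification rate (s^-1), e.g. from
#'   [kcat_from_amplitudes()]; must be below `k2`.
#' @param kcat_sd its standard deviation (default 0).
#' @return a [rate_set()] fragment with `koff_S`, `koff_P`, `kcat`, plus
#'   attributes `koff_S_sd`, `koff_P_sd`.
#' @export
disentangle_rates <- function(fit, kcat, kcat_sd = 0) {
  stopifnot(inherits(fit, "coupled_fit"))
  stop_if_not_scalar_nonneg(kcat, "kcat")
  if (kcat >= fit$k2) {
    stop(sprintf(
      "kcat (%.3g) >= slow rate k2 (%.3g): inconsistent with k2 = kcat + koff_S",
      kcat, fit$k2), call. = FALSE)
  }
  if (kcat / (fit$k1 - fit$k2) > 0.2) {
    warning(paste("kcat is not small against k1 - k2; the two-exponential",
                  "reading of the coupled model is unreliable here"))
  }
  rs <- rate_set(koff_S = fit$k2 - kcat, kcat = kcat, koff_P = fit$k1)
  attr(rs, "koff_S_sd") <- sqrt((fit$k2_se %||% 0)^2 + kcat_sd^2)
  attr(rs, "koff_P_sd") <- fit$k1_se
  rs
}

#' One-call analysis of a coupled dissociation experiment
#'
#' Runs [global_double_exp_fit()], [kcat_from_amplitudes()] and
#' [disentangle_rates()] in sequence.
#'
#' @param exp a [coupled_experiment()].
#' @param ... passed to [global_double_exp_fit()].
#' @return list with `global_fit`, `kcat` (list from
#'   [kcat_from_amplitudes()]) and `rates` (disentangled [rate_set()]).
#' @export
analyze_coupled <- function(exp, ...) {
  gf <- global_double_exp_fit(exp, ...)
  kc <- kcat_from_amplitudes(gf)
  rates <- disentangle_rates(gf, kc$kcat, kc$kcat_sd)
  list(global_fit = gf, kcat = kc, rates = rates)
}
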