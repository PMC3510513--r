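# Fitting the autocorrelation mixture model: reference calibration of the
# pure free / pure bound species, then two-parameter (N, p) extraction of
# the bound fraction with the species parameters held fixed.

fcs_weights <- function(curve) {
  if (is.null(curve$sigma)) rep(1, length(curve$lags))
  else 1 / pmax(curve$sigma, .Machine$double.eps)
}

#' Calibrate single-species FCS reference parameters
#'
#' Weighted least-squares fit of the single-species autocorrelation model to
#' a reference curve recorded with 100% free (`role = "free"`) or ~100%
#' bound (`role = "bound"`) labelled RNA. Fits `N`, `tau_D`, `K_ph` and
#' `tau_T`; the focal-volume structure parameter `kappa` is not identifiable
#' from a single curve and is held fixed. The fitted species parameters are
#' subsequently frozen in [fit_bound_fraction()].
#'
#' Multistart: 8 initial `tau_D` values log-spaced across the interior of
#' the lag range; lowest SSR wins.
#'
#' @param curve an [fcs_curve()] with at least 20 lags spanning >= 3 decades.
#' @param role `"free"` or `"bound"`; recorded in the result label.
#' @param kappa fixed structure parameter (default 5).
#' @return object of classes `fcs_calibration`/`kinfit`; `coef()` gives
#'   `N`, `tau_D`, `K_ph`, `tau_T`; `$species` holds the fitted
#'   [fcs_species()].
#' @export
calibrate_reference <- function(curve, role = c("free", "bound"), kappa = 5) {
  stopifnot(inherits(curve, "fcs_curve"))
  role <- match.arg(role)
  lags <- curve$lags
  if (length(lags) < 20 || log10(max(lags) / min(lags)) < 3) {
    stop("reference curve needs >= 20 lags spanning at least 3 decades",
         call. = FALSE)
  }
  w <- fcs_weights(curve)
  model_fn <- function(par, t) {
    sp <- list(tau_D = par[["tau_D"]], kappa = kappa,
               K_ph = par[["K_ph"]], tau_T = par[["tau_T"]])
    acf_species_factor(t, sp) / par[["N"]]
  }
  resid_fn <- function(par) w * (model_fn(par, lags) - curve$G)
  N0 <- 1 / max(curve$G[1L], .Machine$double.eps)
  tauD_grid <- exp(seq(log(stats::quantile(lags, 0.05)),
                       log(stats::quantile(lags, 0.8)), length.out = 8))
  starts <- lapply(tauD_grid, function(td) {
    c(N = N0, tau_D = as.numeric(td), K_ph = 0.2, tau_T = 2e-6)
  })
  lower <- c(N = 1e-9, tau_D = 1e-9, K_ph = 0, tau_T = 1e-9)
  best <- nls_multistart(resid_fn, starts, lower = lower)
  est <- unlist(best$fit$par)
  se <- lm_std_errors(best$fit)
  out <- new_kinfit(
    "fcs_calibration", est, se,
    data = list(x = lags, y = curve$G), model_fn = model_fn, best = best,
    fixed = list(kappa = kappa, p = if (role == "free") 0 else 1),
    extra = list(role = role,
                 species = suppressWarnings(fcs_species(
                   tau_D = est[["tau_D"]], kappa = kappa,
                   K_ph = est[["K_ph"]], tau_T = est[["tau_T"]])),
                 log_x = TRUE, xlab = "lag (s)", ylab = "G"),
    label = sprintf("single-species ACF calibration (%s reference)", role))
  out
}

#' Extract the bound fraction from a mixed autocorrelation curve
#'
#' Two-parameter weighted fit of the mixture model [acf_mixture()] with the
#' free and bound species parameters fixed at their calibrated values; only
#' the molecule number `N` and the bound fraction `p` (constrained to
#' `[0, 1]`) are adjustable.
#'
#' @param curve an [fcs_curve()].
#' @param free,bound calibrated [fcs_species()] parameter sets; the free
#'   species must diffuse faster (`tau_D` free < `tau_D` bound).
#' @return object of classes `fcs_fit`/`kinfit`; `coef()` gives `N` and `p`.
#' @export
fit_bound_fraction <- function(curve, free, bound) {
  stopifnot(inherits(curve, "fcs_curve"),
            inherits(free, "fcs_species"), inherits(bound, "fcs_species"))
  if (free$tau_D >= bound$tau_D) {
    stop("free species must diffuse faster than bound (tau_D1 < tau_D2)",
         call. = FALSE)
  }
  lags <- curve$lags
  w <- fcs_weights(curve)
  model_fn <- function(par, t) {
    ((1 - par[["p"]]) * acf_species_factor(t, free) +
       par[["p"]] * acf_species_factor(t, bound)) / par[["N"]]
  }
  resid_fn <- function(par) w * (model_fn(par, lags) - curve$G)
  N0 <- 1 / max(curve$G[1L], .Machine$double.eps)
  starts <- lapply(c(0.05, 0.25, 0.5, 0.75, 0.95), function(p0) {
    c(N = N0, p = p0)
  })
  best <- nls_multistart(resid_fn, starts,
                         lower = c(N = 1e-9, p = 0), upper = c(N = Inf, p = 1))
  est <- unlist(best$fit$par)
  se <- lm_std_errors(best$fit)
  new_kinfit(
    "fcs_fit", est, se,
    data = list(x = lags, y = curve$G), model_fn = model_fn, best = best,
    fixed = list(tau_D1 = free$tau_D, tau_D2 = bound$tau_D),
    extra = list(free = free, bound = bound, log_x = TRUE,
                 xlab = "lag (s)", ylab = "G"),
    label = "bound-fraction fit (N, p) with fixed species parameters")
}
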