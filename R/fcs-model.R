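#' Single-species FCS parameters
#'
#' Diffusion and photophysics parameters of one fluorescent species in the
#' confocal volume: characteristic 3-D diffusion time `tau_D`, focal-volume
#' axial-to-lateral ratio `kappa`, and a fast photophysical (dark-state)
#' process with equilibrium amplitude `K_ph` and relaxation time `tau_T`.
#'
#' @param tau_D characteristic diffusion time (s), positive.
#' @param kappa structure parameter (axial/lateral 1/e^2 radius), > 1.
#'   Not identifiable from a single curve and therefore fixed, default 5.
#' @param K_ph photophysics equilibrium amplitude (dimensionless, >= 0).
#' @param tau_T photophysics relaxation time (s), positive. A value above
#'   `tau_D` is physically implausible and triggers a warning, not an error.
#' @return object of class `fcs_species`.
#' @export
fcs_species <- function(tau_D, kappa = 5, K_ph = 0, tau_T = 1e-6) {
  stop_if_not_scalar_nonneg(tau_D, "tau_D")
  stop_if_not_scalar_nonneg(tau_T, "tau_T")
  stop_if_not_scalar_nonneg(K_ph, "K_ph")
  if (tau_D <= 0 || tau_T <= 0) {
    stop("tau_D and tau_T must be positive", call. = FALSE)
  }
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 1) {
    stop("kappa must be a single number > 1", call. = FALSE)
  }
  if (tau_T >= tau_D) {
    warning("tau_T >= tau_D: photophysics slower than diffusion is unusual")
  }
  structure(list(tau_D = tau_D, kappa = kappa, K_ph = K_ph, tau_T = tau_T),
            class = "fcs_species")
}

#' Two-species FCS mixture model
#'
#' The mixture autocorrelation model for a labelled RNA that is either free
#' or enzyme-bound. `N` is the mean number of labelled molecules in the
#' confocal volume and `p` the bound fraction. Equal molecular brightness of
#' the two species is assumed (same single dye), so the mixture weights are
#' molecular fractions.
#'
#' @param N mean number of labelled molecules in the confocal volume (> 0).
#' @param p bound fraction in `[0, 1]`.
#' @param free,bound [fcs_species()] parameters of the free and bound forms.
#' @return object of class `fcs_mixture`.
#' @export
fcs_mixture <- function(N, p, free, bound) {
  stopifnot(inherits(free, "fcs_species"), inherits(bound, "fcs_species"))
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0) {
    stop("N must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be in [0, 1]", call. = FALSE)
  }
  structure(list(N = N, p = p, free = free, bound = bound),
            class = "fcs_mixture")
}

# photophysics x 3-D diffusion factor of one species, vectorized over lag t
acf_species_factor <- function(t, sp) {
  X <- 1 + sp$K_ph * exp(-t / sp$tau_T)
  D <- 1 / ((1 + t / sp$tau_D) * sqrt(1 + t / (sp$kappa^2 * sp$tau_D)))
  X * D
}

#' Evaluate the two-component autocorrelation model
#'
#' \deqn{G(t) = \frac{1}{N}\left[(1-p)X_1(t)D_1(t) + p X_2(t)D_2(t)\right]}
#' with photophysics factor \eqn{X_i(t) = 1 + K_i e^{-t/\tau_{Ti}}} and 3-D
#' diffusion factor
#' \eqn{D_i(t) = (1 + t/\tau_{Di})^{-1}(1 + t/(\kappa^2\tau_{Di}))^{-1/2}}.
#' At `p = 0` or `p = 1` the model reduces exactly to the single-species
#' form; `G` is strictly positive and nonincreasing in the lag.
#'
#' @param t lag time(s) (s), strictly positive.
#' @param model an [fcs_mixture()].
#' @return correlation amplitude(s) G(t).
#' @export
acf_mixture <- function(t, model) {
  stopifnot(inherits(model, "fcs_mixture"))
  if (!is.numeric(t) || anyNA(t) || any(t <= 0)) {
    stop("lag times must be positive", call. = FALSE)
  }
  ((1 - model$p) * acf_species_factor(t, model$free) +
     model$p * acf_species_factor(t, model$bound)) / model$N
}

#' Quasi-logarithmic multi-tau lag grid
#'
#' Lag spacing mimicking a hardware multi-tau correlator: within each octave
#' `[2^k t_min, 2^(k+1) t_min)` the lags are linearly spaced, and octaves
#' cascade up to `t_max`. Default spans 1 us to 1 s.
#'
#' @param t_min,t_max grid limits (s).
#' @param points_per_octave linear points within each doubling (default 14).
#' @return strictly increasing numeric vector of lag times (s).
#' @export
multitau_lags <- function(t_min = 1e-6, t_max = 1, points_per_octave = 14) {
  stopifnot(t_min > 0, t_max > t_min, points_per_octave >= 2)
  n_oct <- ceiling(log2(t_max / t_min))
  lags <- unlist(lapply(seq_len(n_oct) - 1L, function(k) {
    lo <- t_min * 2^k
    seq(lo, 2 * lo, length.out = points_per_octave + 1L)[-(points_per_octave + 1L)]
  }))
  lags <- sort(unique(c(lags, t_max)))
  lags[lags <= t_max]
}

#' Construct an autocorrelation curve object
#'
#' @param lags strictly increasing positive lag times (s).
#' @param G correlation amplitudes, same length as `lags`.
#' @param sigma optional per-lag standard errors (same length).
#' @param duration acquisition time (s), metadata only.
#' @param label free-text provenance, metadata only.
#' @return object of class `fcs_curve`.
#' @export
fcs_curve <- function(lags, G, sigma = NULL, duration = NA_real_,
                      label = "") {
  if (!is.numeric(lags) || anyNA(lags) || any(lags <= 0) ||
      is.unsorted(lags, strictly = TRUE)) {
    stop("'lags' must be strictly increasing and positive", call. = FALSE)
  }
  if (length(G) != length(lags) || anyNA(G)) {
    stop("'G' must match 'lags' in length and contain no NA", call. = FALSE)
  }
  if (!is.null(sigma)) {
    if (length(sigma) != length(lags) || anyNA(sigma) || any(sigma < 0)) {
      stop("'sigma' must be nonnegative and match 'lags'", call. = FALSE)
    }
  }
  structure(list(lags = lags, G = G, sigma = sigma, duration = duration,
                 label = label), class = "fcs_curve")
}

#' @export
print.fcs_curve <- function(x, ...) {
  cat(sprintf("FCS curve: %d lags, %.3g-%.3g s%s\n", length(x$lags),
              min(x$lags), max(x$lags),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}
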