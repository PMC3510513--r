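# Seeded synthetic-data generators with known ground truth. Each generator
# is a pure function of (truth, noise spec incl. seed): the same inputs give
# bit-identical output and the caller's RNG state is left untouched.

#' Noise specification for synthetic data
#'
#' @param kind `"additive_gaussian"` (sigma is absolute, the default for
#'   bound fractions) or `"multiplicative_gaussian"` (sigma is relative, the
#'   default for autocorrelation amplitudes).
#' @param sigma noise magnitude, >= 0.
#' @param seed integer RNG seed; `NULL` uses (and advances) the caller's
#'   RNG state.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("additive_gaussian",
                                "multiplicative_gaussian"),
                       sigma = 0.02, seed = 0L) {
  kind <- match.arg(kind)
  stop_if_not_scalar_nonneg(sigma, "sigma")
  structure(list(kind = kind, sigma = sigma, seed = seed),
            class = "noise_spec")
}

apply_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(x)
  with_seed(noise$seed, {
    eps <- stats::rnorm(length(x))
    if (noise$kind == "additive_gaussian") x + noise$sigma * eps
    else x * (1 + noise$sigma * eps)
  })
}

#' Reference FCS parameters of the free and bound labelled substrate
#'
#' Default single-species truths used throughout the synthetic studies:
#' diffusion times of 0.21 ms (free 14-nt labelled RNA, ~5 kDa) and
#' 0.47 ms (enzyme-bound, ~100 kDa), with a fast dark-state component
#' typical of a cyanine dye.
#'
#' @param kappa fixed structure parameter.
#' @return list with [fcs_species()] elements `free` and `bound`.
#' @export
reference_species <- function(kappa = 5) {
  list(free = fcs_species(tau_D = 0.21e-3, kappa = kappa, K_ph = 0.25,
                          tau_T = 3e-6),
       bound = fcs_species(tau_D = 0.47e-3, kappa = kappa, K_ph = 0.30,
                           tau_T = 4e-6))
}

#' Simulate a noisy autocorrelation curve
#'
#' Evaluates [acf_mixture()] on a multi-tau lag grid and applies the noise
#' model; the `sigma` column of the returned curve records the applied
#' per-lag noise scale (so downstream fits can weight by it).
#'
#' @param model an [fcs_mixture()].
#' @param noise a [noise_spec()].
#' @param lags lag grid (default [multitau_lags()]).
#' @param duration nominal acquisition time (s), metadata.
#' @return an [fcs_curve()].
#' @export
make_acf_curve <- function(model, noise = noise_spec("multiplicative_gaussian"),
                           lags = multitau_lags(), duration = 60) {
  G0 <- acf_mixture(lags, model)
  G <- apply_noise(G0, noise)
  sigma <- if (noise$sigma == 0) NULL else {
    if (noise$kind == "multiplicative_gaussian") noise$sigma * G0
    else rep(noise$sigma, length(G0))
  }
  fcs_curve(lags, G, sigma = sigma, duration = duration,
            label = sprintf("synthetic p=%.2f seed=%s", model$p,
                            format(noise$seed)))
}

#' Simulate an association experiment across enzyme concentrations
#'
#' For each enzyme concentration, integrates the full second-order binding
#' ODE ([simulate_association()]), samples it at a fixed cadence and applies
#' noise. Ground truth is embedded in the result attributes.
#'
#' @param kon association rate (M^-1 s^-1).
#' @param koff dissociation rate (s^-1).
#' @param CS labelled RNA concentration (M), default 10 nM.
#' @param CE enzyme concentrations (M), default 0.125-0.75 uM.
#' @param cadence sampling interval (s), default 30.
#' @param duration monitored time (s), default 1200 (20 min).
#' @param noise a [noise_spec()]; seeds per curve are derived as
#'   `seed + index - 1`.
#' @return list of [bound_fraction_series()], one per `CE`, with attribute
#'   `truth = c(kon, koff)`.
#' @export
make_association_experiment <- function(kon, koff, CS = 10e-9,
                                        CE = c(0.125, 0.25, 0.5, 0.75) * 1e-6,
                                        cadence = 30, duration = 1200,
                                        noise = noise_spec(sigma = 0.02)) {
  times <- seq(cadence, duration, by = cadence)
  out <- lapply(seq_along(CE), function(i) {
    traj <- simulate_association(CS, CE[i], kon, koff, times)
    ns <- noise
    if (!is.null(ns$seed)) ns$seed <- ns$seed + i - 1L
    bound_fraction_series(times, apply_noise(traj$p, ns), CE = CE[i],
                          CS = CS, kind = "association")
  })
  attr(out, "truth") <- c(kon = kon, koff = koff)
  out
}

#' Simulate an equilibrium titration
#'
#' Bound fractions from the exact isotherm [equilibrium_occupancy()] on a
#' log-spaced enzyme grid (default 10 nM to 10 uM, 12 points), plus noise.
#'
#' @param Kd equilibrium dissociation constant (M).
#' @param CS labelled RNA concentration (M), default 10 nM.
#' @param CE enzyme concentrations (M); default 12 log-spaced points
#'   between 10 nM and 10 uM.
#' @param noise a [noise_spec()] (default additive, sigma 0.03).
#' @return data frame with columns `CE`, `p`, attribute `truth = Kd`.
#' @export
make_titration <- function(Kd, CS = 10e-9,
                           CE = exp(seq(log(10e-9), log(10e-6),
                                        length.out = 12)),
                           noise = noise_spec(sigma = 0.03)) {
  p <- apply_noise(equilibrium_occupancy(CS, CE, Kd), noise)
  out <- data.frame(CE = CE, p = p)
  attr(out, "truth") <- c(Kd = Kd)
  attr(out, "CS") <- CS
  out
}

# dilution-chase sampling schedule: dense early (fast component), sparser
# later, truncated once the noiseless signal has decayed to 5% of p(0) (or
# at 3 h)
coupled_sample_times <- function(rates, fS0, fP0, max_t = 10800) {
  tt <- c(seq(30, 600, by = 30), seq(660, 3600, by = 60),
          seq(3780, max_t, by = 180))
  p <- dilution_response(rates, fS0, fP0, tt)$p_exact
  p0 <- fS0 + fP0
  keep <- which(p >= 0.05 * p0)
  stop_i <- if (length(keep)) min(length(tt), max(keep) + 1L) else 8L
  tt[seq_len(max(stop_i, 8L))]
}

#' Simulate a coupled dissociation-catalysis experiment
#'
#' For each incubation time, computes the pre-dilution composition
#' ([pre_dilution_state()]), evaluates the exact post-dilution response
#' ([dilution_response()], exact form, not the two-term approximation),
#' samples it on the chase schedule and applies noise.
#'
#' @param rates a [rate_set()] with `koff_S`, `kcat`, `koff_P` and `Kd_P`.
#' @param CS,CE pre-dilution concentrations (M); defaults 2 uM and 6 uM.
#' @param T_inc incubation times (s); default
#'   `c(5, 62, 121, 177, 231, 293)` minutes.
#' @param noise a [noise_spec()]; per-curve seeds are `seed + index - 1`.
#' @return a [coupled_experiment()] with attribute `truth` (the rate set)
#'   and attribute `initial_states` (per-T pre-dilution fractions).
#' @export
make_coupled_experiment <- function(rates, CS = 2e-6, CE = 6e-6,
                                    T_inc = c(5, 62, 121, 177, 231, 293) * 60,
                                    noise = noise_spec(sigma = 0.02)) {
  stopifnot(inherits(rates, "rate_set"))
  if (is.na(rates$Kd_P)) stop("rates must include Kd_P", call. = FALSE)
  states <- lapply(T_inc, function(Ti) {
    pre_dilution_state(CS, CE, rates$Kd_P, rates$kcat, Ti)
  })
  series <- lapply(seq_along(T_inc), function(i) {
    st <- states[[i]]
    tt <- coupled_sample_times(rates, st[["fS0"]], st[["fP0_bound"]])
    p <- dilution_response(rates, st[["fS0"]], st[["fP0_bound"]], tt)$p_exact
    ns <- noise
    if (!is.null(ns$seed)) ns$seed <- ns$seed + i - 1L
    bound_fraction_series(tt, apply_noise(p, ns), CE = CE / 4000,
                          CS = CS / 4000, kind = "dissociation")
  })
  out <- coupled_experiment(series, T_inc, CS, CE)
  attr(out, "truth") <- rates
  attr(out, "initial_states") <- do.call(rbind, states)
  out
}

#' Printed apparent binding parameters used as simulation ground truths
#'
#' The apparent kon, koff and Kd of each substrate/enzyme-variant pair
#' (27 C, 1 M NaCl), as published; used here only as ground truths for the
#' synthetic recovery studies, never as measurements. Units: kon in
#' 10^3 M^-1 s^-1, koff in 10^-3 s^-1, Kd in uM. `NA` marks values not
#' determinable for reactive pairs.
#'
#' @return data frame with columns `substrate`, `enzyme`, `kon`, `kon_sd`,
#'   `koff`, `koff_sd`, `Kd`, `Kd_sd`.
#' @export
binding_truths <- function() {
  tab <- rbind(
    c("Sub-U", "WT",          27,  1,   NA,  NA,   NA,    NA),
    c("Sub-U", "D85A",        17,  1,   0.69, 0.09, 0.031, 0.002),
    c("Sub-U", "DEL7",        18,  3,   12,   3,    0.23,  0.08),
    c("Sub-U", "R154Q",       11,  3,   11,   2,    0.47,  0.05),
    c("Sub-U", "RNA only",    NA,  NA,  27,   5,    1.5,   0.1),
    c("Sub-Psi", "WT",        23,  5,   12,   1,    1.1,   0.2),
    c("Sub-Psi", "D85A",      22,  4,   11,   1,    0.9,   0.1),
    c("Sub-Psi", "DEL7",      15,  3,   14,   1,    0.9,   0.1),
    c("Sub-Psi", "R154Q",     18,  8,   16,   2,    0.8,   0.1),
    c("Sub-Psi", "RNA only",  NA,  NA,  17,   5,    1.72,  0.15),
    c("Sub-U", "dGar1",       12,  1,   NA,   NA,   NA,    NA),
    c("Sub-U", "dGar1/D85A",  26,  1,   0.54, 0.04, 0.036, 0.002),
    c("Sub-U", "dGar1/DEL7",  8.4, 0.4, 7.8,  0.7,  0.15,  0.01),
    c("Sub-U", "dGar1/R154Q", 8,   2,   7,    1,    0.42,  0.06),
    c("Sub-Psi", "dGar1",     27,  5,   5,    1,    0.32,  0.04),
    c("Sub-Psi", "dGar1/D85A", 35, 4,   5,    1,    0.20,  0.03),
    c("Sub-Psi", "dGar1/DEL7", 22, 3,   12,   1,    0.7,   0.1),
    c("Sub-Psi", "dGar1/R154Q", 24, 11, 16,   4,    0.83,  0.09),
    c("Sub-C", "WT",          NA,  NA,  42,   9,    3.5,   0.1))
  out <- data.frame(substrate = tab[, 1L], enzyme = tab[, 2L],
                    stringsAsFactors = FALSE)
  num <- apply(tab[, 3:8], 2, as.numeric)
  colnames(num) <- c("kon", "kon_sd", "koff", "koff_sd", "Kd", "Kd_sd")
  cbind(out, num)
}

#' Ground-truth rate set of the slowly reacting Gar1-less complex
#'
#' The coupled-experiment truth: substrate off-rate 0.45e-3 s^-1, product
#' off-rate 6.4e-3 s^-1, on-enzyme modification rate 0.19e-3 s^-1, product
#' Kd 0.32 uM, and the single-turnover rate 0.08e-3 s^-1 measured by the
#' activity assay.
#'
#' @return a [rate_set()] with attribute `kcat_prime` (s^-1).
#' @export
coupled_truth <- function() {
  rs <- rate_set(koff_S = 0.45e-3, kcat = 0.19e-3, koff_P = 6.4e-3,
                 Kd_P = 0.32e-6)
  attr(rs, "kcat_prime") <- 0.08e-3
  rs
}
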