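#' Kinetic and thermodynamic parameter bundle for the binding/modification scheme
#'
#' Collects the rate constants of the minimal substrate-turnover scheme
#' \deqn{E + S \rightleftharpoons ES \xrightarrow{k_{cat}} EP \rightleftharpoons E + P}
#' together with the apparent equilibrium dissociation constants of the
#' substrate and product complexes. The constants are stored independently:
#' apparent parameters measured by different experiments need not satisfy
#' `Kd = koff/kon`, and the constructor never reconciles them silently.
#'
#' @param kon association rate (M^-1 s^-1), shared by substrate and product.
#' @param koff_S substrate dissociation rate (s^-1).
#' @param kcat on-enzyme modification rate (s^-1).
#' @param koff_P product dissociation rate (s^-1).
#' @param Kd_S,Kd_P apparent equilibrium dissociation constants (M).
#' @return an object of class `rate_set` (a named list).
#' @examples
#' # apparent rates of the slowly reacting Gar1-less enzyme
#' rate_set(koff_S = 0.45e-3, kcat = 0.19e-3, koff_P = 6.4e-3,
#'          Kd_P = 0.32e-6)
#' @export
rate_set <- function(kon = NA_real_, koff_S = NA_real_, kcat = NA_real_,
                     koff_P = NA_real_, Kd_S = NA_real_, Kd_P = NA_real_) {
  vals <- list(kon = kon, koff_S = koff_S, kcat = kcat,
               koff_P = koff_P, Kd_S = Kd_S, Kd_P = Kd_P)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.na(v)) stop_if_not_scalar_nonneg(v, nm)
  }
  structure(vals, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Rate set (SI units):\n")
  for (nm in names(x)) {
    if (!is.na(x[[nm]])) cat(sprintf("  %-7s %.6g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Define a general first-order kinetic scheme
#'
#' A linear scheme is a set of labelled states connected by first-order
#' transitions; it generalises both the post-dilution limit of the turnover
#' scheme (where re-association is negligible) and sequential loading/release
#' models such as ES1 -> ES2 -> EP2 -> EP1.
#'
#' @param states character vector of state labels.
#' @param transitions data frame with columns `from`, `to`, `rate` (s^-1).
#' @param init named numeric vector of initial occupancies; must be
#'   nonnegative and sum to 1.
#' @return an object of class `linear_scheme`.
#' @seealso [simulate_linear_scheme()]
#' @export
linear_scheme <- function(states, transitions, init) {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state labels", call. = FALSE)
  tr <- as.data.frame(transitions)
  if (!all(c("from", "to", "rate") %in% names(tr))) {
    stop("'transitions' needs columns from, to, rate", call. = FALSE)
  }
  for (i in seq_len(nrow(tr))) {
    if (!tr$from[i] %in% states || !tr$to[i] %in% states) {
      stop(sprintf("transition %s -> %s refers to an unknown state",
                   tr$from[i], tr$to[i]), call. = FALSE)
    }
    if (!is.finite(tr$rate[i]) || tr$rate[i] < 0) {
      stop(sprintf("transition %s -> %s has a negative or non-finite rate",
                   tr$from[i], tr$to[i]), call. = FALSE)
    }
  }
  init <- init[states]
  if (anyNA(init) || any(init < 0)) {
    stop("'init' must give a nonnegative occupancy for every state",
         call. = FALSE)
  }
  if (abs(sum(init) - 1) > 1e-10) {
    stop("initial occupancies must sum to 1", call. = FALSE)
  }
  structure(list(states = states, transitions = tr, init = init),
            class = "linear_scheme")
}

#' Integrate a first-order scheme numerically
#'
#' Numeric ODE integration (stiff-capable `lsoda`) of the occupancy dynamics
#' of a [linear_scheme()]. This is the package's brute-force oracle: closed
#' forms elsewhere are validated against it.
#'
#' @param scheme a [linear_scheme()].
#' @param times strictly increasing nonnegative sample times (s).
#' @param rtol,atol integration tolerances; defaults are tight because rate
#'   constants in one scheme can span four orders of magnitude.
#' @return a data frame with column `time_s` and one occupancy column per
#'   state; occupancies at every time sum to 1 to within integration
#'   tolerance.
#' @export
simulate_linear_scheme <- function(scheme, times, rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(scheme, "linear_scheme"))
  check_times(times)
  n <- length(scheme$states)
  # generator matrix: d y = Q y, Q[i, j] = rate(j -> i) for i != j
  Q <- matrix(0, n, n, dimnames = list(scheme$states, scheme$states))
  for (i in seq_len(nrow(scheme$transitions))) {
    fr <- scheme$transitions$from[i]
    to <- scheme$transitions$to[i]
    k <- scheme$transitions$rate[i]
    Q[to, fr] <- Q[to, fr] + k
    Q[fr, fr] <- Q[fr, fr] - k
  }
  t_out <- if (times[1L] > 0) c(0, times) else times
  deriv <- function(t, y, parms) list(as.vector(Q %*% y))
  sol <- deSolve::lsoda(y = scheme$init, times = t_out, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  names(sol)[1L] <- "time_s"
  sol[match(times, t_out), , drop = FALSE]
}

#' Exact bound-fraction response after dilution of a reacting complex
#'
#' After a large dilution, re-association is negligible and the bound RNA
#' fraction obeys the linear system ES -> S (rate `koff_S`), ES -> EP
#' (`kcat`), EP -> P (`koff_P`). Starting from bound substrate fraction
#' `fS0` and bound product fraction `fP0`, the observed bound fraction
#' p(t) = ES(t) + EP(t) is a sum of two exponentials with rates
#' `kcat + koff_S` (slow) and `koff_P` (fast):
#' \deqn{p(t) = f_{S0}\left(1 + \frac{k_{cat}}{k_{off,P}-k_{cat}-k_{off,S}}\right)
#'   e^{-(k_{cat}+k_{off,S})t} +
#'   \left(f_{P0} - \frac{f_{S0}k_{cat}}{k_{off,P}-k_{cat}-k_{off,S}}\right)
#'   e^{-k_{off,P}t}}
#' The conversion-flux cross term (the `kcat/(koff_P - kcat - koff_S)`
#' factor) quantifies substrate converted to product *during* the chase.
#' The commonly used two-term reading drops that cross term, assigning
#' amplitude `fS0` to the slow rate and `fP0` to the fast rate; both forms
#' are returned together with their maximum absolute deviation so the
#' approximation can be audited.
#'
#' @param rates a [rate_set()] with `koff_S`, `kcat`, `koff_P` set.
#' @param fS0 bound unmodified-substrate fraction at t = 0.
#' @param fP0 bound product fraction at t = 0.
#' @param times nonnegative sample times (s), strictly increasing.
#' @return list with elements `times`, `p_exact`, `p_approx`, `max_dev`
#'   (max |exact - approx| over `times`), `rates` (named: `k_fast`,
#'   `k_slow`), `amplitudes` (named: exact `A_fast`, `A_slow`) and
#'   `degenerate` (TRUE when the two decay rates coincide and the confluent
#'   `t e^{-kt}` form was used).
#' @export
dilution_response <- function(rates, fS0, fP0, times) {
  stopifnot(inherits(rates, "rate_set"))
  stop_if_not_scalar_nonneg(fS0, "fS0")
  stop_if_not_scalar_nonneg(fP0, "fP0")
  if (fS0 + fP0 > 1 + 1e-12) stop("fS0 + fP0 must not exceed 1", call. = FALSE)
  check_times(times)
  koff_S <- rates$koff_S; kcat <- rates$kcat; koff_P <- rates$koff_P
  if (anyNA(c(koff_S, kcat, koff_P))) {
    stop("rates must provide koff_S, kcat and koff_P", call. = FALSE)
  }
  k_slow <- kcat + koff_S
  k_fast <- koff_P
  gap <- k_fast - k_slow
  scale <- max(k_fast, k_slow, .Machine$double.eps)
  degenerate <- abs(gap) < 1e-9 * scale

  if (!degenerate) {
    cross <- fS0 * kcat / gap
    A_slow <- fS0 + cross
    A_fast <- fP0 - cross
    p_exact <- A_slow * exp(-k_slow * times) + A_fast * exp(-k_fast * times)
  } else {
    # confluent limit: EP picks up a t*exp(-kt) secular term
    A_slow <- fS0
    A_fast <- fP0
    p_exact <- (fS0 + fP0) * exp(-k_slow * times) +
      fS0 * kcat * times * exp(-k_slow * times)
  }
  p_approx <- fS0 * exp(-k_slow * times) + fP0 * exp(-k_fast * times)
  list(times = times, p_exact = p_exact, p_approx = p_approx,
       max_dev = max(abs(p_exact - p_approx)),
       rates = c(k_fast = k_fast, k_slow = k_slow),
       amplitudes = c(A_fast = A_fast, A_slow = A_slow),
       degenerate = degenerate)
}

#' Composition of the reaction mixture at the end of a pre-incubation
#'
#' During pre-incubation at enzyme excess, all unmodified substrate is
#' enzyme-bound (binding is much faster than modification, and the enzyme
#' concentration far exceeds the substrate Kd), so the unmodified fraction
#' decays as `exp(-kcat * T)`. Accumulated product partitions between free
#' and enzyme-bound states by exact mass action against the enzyme not
#' occupied by substrate; the closed-form quadratic root is used rather than
#' the `CE/(CE + Kd)` excess approximation, which is inexact when the
#' available enzyme is not far above `Kd_P`.
#'
#' @param CS total labelled RNA concentration (M).
#' @param CE total enzyme concentration (M).
#' @param Kd_P product equilibrium dissociation constant (M).
#' @param kcat on-enzyme modification rate (s^-1).
#' @param T_inc incubation time (s).
#' @return named numeric vector `c(fS0, fP0_bound, fP0_free)`; fractions of
#'   total labelled RNA, summing to 1.
#' @export
pre_dilution_state <- function(CS, CE, Kd_P, kcat, T_inc) {
  stop_if_not_scalar_nonneg(CS, "CS"); stop_if_not_scalar_nonneg(CE, "CE")
  stop_if_not_scalar_nonneg(Kd_P, "Kd_P")
  stop_if_not_scalar_nonneg(kcat, "kcat")
  stop_if_not_scalar_nonneg(T_inc, "T_inc")
  if (CS <= 0 || CE <= 0) stop("CS and CE must be positive", call. = FALSE)
  fS <- exp(-kcat * T_inc)
  CP <- CS * (1 - fS)                 # total product concentration
  E_avail <- max(CE - CS * fS, 0)     # enzyme not sequestered by substrate
  if (CP <= 0 || E_avail <= 0) {
    return(c(fS0 = fS, fP0_bound = 0, fP0_free = 1 - fS))
  }
  s <- E_avail + CP + Kd_P
  B <- (s - sqrt(s * s - 4 * E_avail * CP)) / 2   # bound product (M)
  c(fS0 = fS, fP0_bound = B / CS, fP0_free = (CP - B) / CS)
}

#' Equilibrium bound fraction under the quadratic tight-binding isotherm
#'
#' Exact mass-action occupancy of labelled RNA at total concentrations
#' `CS` (RNA) and `CE` (enzyme), without the ligand-excess approximation:
#' \deqn{p = \frac{(C_S + C_E + K_d) - \sqrt{(C_S + C_E + K_d)^2 - 4 C_S C_E}}{2 C_S}}
#' This is the forward model for titration fitting.
#'
#' @param CS total labelled RNA concentration (M), positive scalar.
#' @param CE total enzyme concentration(s) (M), nonnegative vector.
#' @param Kd equilibrium dissociation constant (M), nonnegative.
#' @return bound fraction(s) in `[0, min(1, CE/CS)]`, nondecreasing in `CE`.
#' @examples
#' equilibrium_occupancy(10e-9, c(10e-9, 1e-7, 1e-6), 31e-9)
#' @export
equilibrium_occupancy <- function(CS, CE, Kd) {
  stop_if_not_scalar_nonneg(CS, "CS")
  if (CS <= 0) stop("CS must be positive", call. = FALSE)
  stop_if_not_scalar_nonneg(Kd, "Kd")
  if (!is.numeric(CE) || anyNA(CE) || any(CE < 0)) {
    stop("CE must be nonnegative", call. = FALSE)
  }
  s <- CS + CE + Kd
  disc <- s * s - 4 * CS * CE
  disc[disc < 0] <- 0   # analytically nonnegative; guard rounding
  p <- (s - sqrt(disc)) / (2 * CS)
  pmin(pmax(p, 0), pmin(1, CE / CS))
}

#' Simulate a bimolecular association time course
#'
#' Integrates the full second-order binding ODE
#' `dB/dt = kon (CS - B)(CE - B) - koff B` (no pseudo-first-order shortcut)
#' and returns the bound fraction `p = B/CS`. At long times the trajectory
#' converges to [equilibrium_occupancy()] with `Kd = koff/kon`; at enzyme
#' excess it is well approximated by
#' `p_eq (1 - exp(-kobs t))` with `kobs = kon CE + koff`, which is what the
#' association fitters assume.
#'
#' @param CS labelled RNA concentration (M).
#' @param CE enzyme concentration (M), must be positive.
#' @param kon association rate (M^-1 s^-1).
#' @param koff dissociation rate (s^-1).
#' @param times nonnegative sample times (s), strictly increasing.
#' @param p0 bound fraction at t = 0 (default 0, mixing starts unbound).
#' @param rtol,atol integration tolerances.
#' @return data frame with columns `time_s`, `p`.
#' @export
simulate_association <- function(CS, CE, kon, koff, times, p0 = 0,
                                 rtol = 1e-10, atol = 1e-14) {
  stop_if_not_scalar_nonneg(CS, "CS"); stop_if_not_scalar_nonneg(CE, "CE")
  stop_if_not_scalar_nonneg(kon, "kon"); stop_if_not_scalar_nonneg(koff, "koff")
  if (CE <= 0) stop("CE must be positive", call. = FALSE)
  check_times(times)
  t_out <- if (times[1L] > 0) c(0, times) else times
  deriv <- function(t, y, parms) {
    B <- y[1L]
    list(kon * (CS - B) * (CE - B) - koff * B)
  }
  sol <- deSolve::lsoda(y = c(B = p0 * CS), times = t_out, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol * max(CS, 1e-12))
  B <- as.data.frame(sol)$B[match(times, t_out)]
  data.frame(time_s = times, p = B / CS)
}

#' Simulate the dilution chase of a reacting complex at full mass action
#'
#' Integrates scheme concentrations (S, ES, EP, P, E) after dilution,
#' optionally retaining re-association (`kon` acting on both S and P). With
#' re-association off this reduces to the linear post-dilution system solved
#' analytically by [dilution_response()]; with it on, the simulation
#' quantifies how good the no-re-association assumption is at the diluted
#' concentrations.
#'
#' @param rates a [rate_set()]; `kon` is only needed when
#'   `reassociation = TRUE`.
#' @param CS total labelled RNA concentration after dilution (M).
#' @param CE total enzyme concentration after dilution (M).
#' @param fS0,fP0_bound,fP0_free initial fractions of labelled RNA.
#' @param times sample times (s).
#' @param reassociation include second-order rebinding terms?
#' @return data frame with `time_s`, per-species concentrations (M) and the
#'   observed bound fraction `p = (ES + EP)/CS`.
#' @export
simulate_dilution <- function(rates, CS, CE, fS0, fP0_bound, fP0_free, times,
                              reassociation = FALSE) {
  stopifnot(inherits(rates, "rate_set"))
  check_times(times)
  fr <- c(fS0, fP0_bound, fP0_free)
  if (any(fr < 0) || sum(fr) > 1 + 1e-9) {
    stop("initial fractions must be nonnegative and sum to at most 1",
         call. = FALSE)
  }
  kon <- if (reassociation) rates$kon else 0
  if (reassociation && is.na(kon)) {
    stop("reassociation = TRUE requires 'kon' in the rate set", call. = FALSE)
  }
  y0 <- c(S = CS * (1 - sum(fr)), ES = CS * fS0,
          EP = CS * fP0_bound, P = CS * fP0_free)
  deriv <- function(t, y, parms) {
    E_free <- CE - y["ES"] - y["EP"]
    dES <- kon * E_free * y["S"] - (rates$koff_S + rates$kcat) * y["ES"]
    dEP <- rates$kcat * y["ES"] + kon * E_free * y["P"] -
      rates$koff_P * y["EP"]
    dS <- rates$koff_S * y["ES"] - kon * E_free * y["S"]
    dP <- rates$koff_P * y["EP"] - kon * E_free * y["P"]
    list(c(dS, dES, dEP, dP))
  }
  t_out <- if (times[1L] > 0) c(0, times) else times
  sol <- deSolve::lsoda(y = y0, times = t_out, func = deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-14 * max(CS, 1e-12))
  sol <- as.data.frame(sol)[match(times, t_out), ]
  names(sol)[1L] <- "time_s"
  sol$E_free <- CE - sol$ES - sol$EP
  sol$p <- (sol$ES + sol$EP) / CS
  rownames(sol) <- NULL
  sol
}
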