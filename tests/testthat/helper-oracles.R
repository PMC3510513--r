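# Independent brute-force oracles used across the suite.

# bisection root of the mass-action binding equilibrium:
# (CE - B)(CS - B) = Kd * B, B in [0, min(CS, CE)]
bisect_occupancy <- function(CS, CE, Kd, iters = 200) {
  f <- function(B) (CE - B) * (CS - B) - Kd * B
  lo <- 0; hi <- min(CS, CE)
  if (hi == 0) return(0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / CS
}

# bisection partition of product between free and enzyme-bound states,
# with E_avail the enzyme not occupied by substrate
bisect_product_bound <- function(E_avail, CP, Kd) {
  f <- function(B) (E_avail - B) * (CP - B) - Kd * B
  lo <- 0; hi <- min(E_avail, CP)
  if (hi == 0) return(0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# the post-dilution three-state linear system as a deSolve scheme
scheme3_post_dilution <- function(rates, fS0, fP0) {
  linear_scheme(
    c("ES", "EP", "S", "P"),
    data.frame(from = c("ES", "ES", "EP"), to = c("S", "EP", "P"),
               rate = c(rates$koff_S, rates$kcat, rates$koff_P)),
    init = c(ES = fS0, EP = fP0, S = 0, P = 1 - fS0 - fP0))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected),
                                              .Machine$double.eps)), tol)
}
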