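sp <- reference_species()

test_that("mixture model endpoints, limits and linearity", {
  lags <- multitau_lags()
  free_only <- fcs_mixture(N = 4, p = 0, free = sp$free, bound = sp$bound)
  bound_only <- fcs_mixture(N = 4, p = 1, free = sp$free, bound = sp$bound)
  mix <- fcs_mixture(N = 4, p = 0.37, free = sp$free, bound = sp$bound)

  G_free <- acf_mixture(lags, free_only)
  G_bound <- acf_mixture(lags, bound_only)
  G_mix <- acf_mixture(lags, mix)

  # endpoints reduce to the single-species forms
  expect_equal(G_free,
               fcskinetics:::acf_species_factor(lags, sp$free) / 4,
               tolerance = 1e-15)
  expect_equal(G_bound,
               fcskinetics:::acf_species_factor(lags, sp$bound) / 4,
               tolerance = 1e-15)
  # mixture linearity at shared N
  expect_equal(G_mix, (1 - 0.37) * G_free + 0.37 * G_bound,
               tolerance = 1e-15)

  # decorrelation: G at 1e4 * tau_D2 below 1e-3 of the first lag
  expect_lt(acf_mixture(1e4 * sp$bound$tau_D, mix) / G_mix[1L], 1e-3)

  # zero-lag limit (1/N)[(1-p)(1+K1) + p(1+K2)]
  G0 <- ((1 - 0.37) * (1 + sp$free$K_ph) + 0.37 * (1 + sp$bound$K_ph)) / 4
  expect_equal(acf_mixture(1e-12, mix), G0, tolerance = 1e-5)

  expect_error(acf_mixture(c(-1, 1e-5), mix), "positive")
})

test_that("G is monotone nonincreasing for random valid parameter draws", {
  set.seed(21)
  lags <- multitau_lags()
  for (i in 1:20) {
    m <- fcs_mixture(
      N = stats::runif(1, 0.5, 50), p = stats::runif(1),
      free = fcs_species(tau_D = 10^stats::runif(1, -4.5, -3.3),
                         K_ph = stats::runif(1, 0, 1),
                         tau_T = 10^stats::runif(1, -6.5, -5.5)),
      bound = fcs_species(tau_D = 10^stats::runif(1, -3.3, -2.5),
                          K_ph = stats::runif(1, 0, 1),
                          tau_T = 10^stats::runif(1, -6.5, -5.5)))
    G <- acf_mixture(lags, m)
    expect_true(all(G > 0))
    expect_true(all(diff(G) <= 1e-15))
  }
})

test_that("multi-tau lag grid is strictly increasing and spans the range", {
  lags <- multitau_lags()
  expect_true(all(diff(lags) > 0))
  expect_equal(min(lags), 1e-6)
  expect_equal(max(lags), 1)
  expect_gt(length(lags), 100)
})

test_that("reference calibration recovers parameters", {
  model <- fcs_mixture(N = 5, p = 0, free = sp$free, bound = sp$bound)
  crv <- make_acf_curve(model, noise_spec("multiplicative_gaussian", 0, 1))
  cal <- calibrate_reference(crv, "free")
  expect_rel_equal(coef(cal)[["tau_D"]], sp$free$tau_D, 1e-6)
  expect_rel_equal(coef(cal)[["N"]], 5, 1e-6)
  expect_true(cal$converged)

  # guard: too few lags / too narrow a span
  short <- fcs_curve(crv$lags[1:10], crv$G[1:10])
  expect_error(calibrate_reference(short, "free"), "3 decades|20 lags")
})

test_that("noisy calibration recovers tau_D within 5% in >= 90% of seeds", {
  model <- fcs_mixture(N = 5, p = 0, free = sp$free, bound = sp$bound)
  taus <- vapply(1:50, function(i) {
    crv <- make_acf_curve(model,
                          noise_spec("multiplicative_gaussian", 0.02, i))
    coef(calibrate_reference(crv, "free"))[["tau_D"]]
  }, numeric(1))
  expect_gte(mean(abs(taus - sp$free$tau_D) / sp$free$tau_D < 0.05), 0.9)
})

test_that("calibrating a bound-species curve as free is detectable", {
  model <- fcs_mixture(N = 5, p = 1, free = sp$free, bound = sp$bound)
  crv <- make_acf_curve(model, noise_spec("multiplicative_gaussian", 0.02, 4))
  cal <- calibrate_reference(crv, "free")   # mislabeled on purpose
  expect_true(cal$converged)
  dev <- abs(coef(cal)[["tau_D"]] - sp$free$tau_D)
  expect_gt(dev, 2 * cal$se[["tau_D"]])
})

test_that("bound-fraction fit round-trips exactly on noiseless curves", {
  for (p_true in c(0, 0.25, 0.6, 1)) {
    for (N_true in c(2, 20)) {
      m <- fcs_mixture(N = N_true, p = p_true, free = sp$free,
                       bound = sp$bound)
      crv <- make_acf_curve(m, noise_spec("multiplicative_gaussian", 0, 1))
      fit <- fit_bound_fraction(crv, sp$free, sp$bound)
      expect_lt(abs(coef(fit)[["p"]] - p_true), 1e-6)
      expect_rel_equal(coef(fit)[["N"]], N_true, 1e-6)
    }
  }
  expect_error(fit_bound_fraction(
    make_acf_curve(fcs_mixture(4, 0.5, sp$free, sp$bound),
                   noise_spec(sigma = 0)),
    sp$bound, sp$free), "faster")
})

test_that("noisy bound-fraction estimates are accurate and pure-free reads ~0", {
  m <- fcs_mixture(N = 5, p = 0.5, free = sp$free, bound = sp$bound)
  ps <- vapply(1:50, function(i) {
    crv <- make_acf_curve(m, noise_spec("multiplicative_gaussian", 0.02, i))
    coef(fit_bound_fraction(crv, sp$free, sp$bound))[["p"]]
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.03)

  m0 <- fcs_mixture(N = 5, p = 0, free = sp$free, bound = sp$bound)
  crv0 <- make_acf_curve(m0, noise_spec("multiplicative_gaussian", 0.02, 9))
  expect_lte(coef(fit_bound_fraction(crv0, sp$free, sp$bound))[["p"]], 0.02)
})

test_that("p identifiability degrades as the diffusion times converge", {
  # documented limitation: the bound-fraction uncertainty grows without
  # bound as tau_D2/tau_D1 -> 1; near-coincident diffusion times leave p
  # essentially unconstrained at 2% noise
  free <- sp$free
  se_at_ratio <- function(ratio) {
    bound <- fcs_species(tau_D = ratio * free$tau_D, K_ph = free$K_ph,
                         tau_T = free$tau_T)
    m <- fcs_mixture(N = 5, p = 0.5, free = free, bound = bound)
    crv <- make_acf_curve(m, noise_spec("multiplicative_gaussian", 0.02, 2))
    fit_bound_fraction(crv, free, bound)$se[["p"]]
  }
  se_close <- se_at_ratio(1.02)
  se_mid <- se_at_ratio(1.3)
  se_wide <- se_at_ratio(0.47 / 0.21)
  expect_gt(se_close, 0.1)
  expect_gt(se_close, se_mid)
  expect_gt(se_mid, se_wide)
})
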