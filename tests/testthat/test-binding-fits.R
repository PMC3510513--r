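test_that("association fit recovers noiseless parameters exactly", {
  tt <- seq(30, 1200, by = 30)
  p <- 0.8 * (1 - exp(-5e-3 * tt))
  s <- bound_fraction_series(tt, p, CE = 0.5e-6, CS = 10e-9, "association")
  fit <- fit_association(s)
  expect_rel_equal(coef(fit)[["kobs"]], 5e-3, 1e-8)
  expect_rel_equal(coef(fit)[["p_eq"]], 0.8, 1e-8)

  # decreasing data is a kind mismatch
  s_bad <- bound_fraction_series(tt, 0.8 * exp(-5e-3 * tt),
                                 kind = "association")
  expect_error(fit_association(s_bad), "kind mismatch")
})

test_that("kobs from the ODE trajectory matches the pseudo-first-order law", {
  tt <- seq(10, 900, by = 10)
  tr <- simulate_association(10e-9, 0.5e-6, 2.7e4, 1.2e-2, tt)
  s <- bound_fraction_series(tt, tr$p, CE = 0.5e-6, CS = 10e-9,
                             "association")
  kobs <- coef(fit_association(s))[["kobs"]]
  expect_lt(abs(kobs - (2.7e4 * 0.5e-6 + 1.2e-2)) / (2.7e4 * 0.5e-6 + 1.2e-2),
            0.02)
})

test_that("kobs increases strictly with enzyme concentration", {
  ex <- make_association_experiment(27e3, 12e-3,
                                    noise = noise_spec(sigma = 0))
  kobs <- vapply(ex, function(s) coef(fit_association(s))[["kobs"]],
                 numeric(1))
  expect_true(all(diff(kobs) > 0))
})

test_that("kobs-vs-concentration regression behaves like a proper line fit", {
  CE <- c(0.125, 0.25, 0.5, 0.75) * 1e-6
  kobs <- 2.7e4 * CE + 1.2e-2
  # exact collinear input: stats warns that the fit is "essentially perfect"
  fit <- suppressWarnings(fit_kobs_line(CE, kobs))
  expect_rel_equal(fit$kon, 2.7e4, 1e-10)
  expect_rel_equal(fit$intercept, 1.2e-2, 1e-10)
  expect_false(fit$intercept_reliable)

  # unit invariance: CE in uM rescales the slope by exactly 1e6
  fit_uM <- suppressWarnings(fit_kobs_line(CE * 1e6, kobs))
  expect_rel_equal(fit$kon, fit_uM$kon * 1e6, 1e-10)

  # reorder and uniform error-scaling invariance
  set.seed(5)
  kobs_n <- kobs * (1 + 0.05 * stats::rnorm(4))
  sd <- c(0.1, 0.2, 0.15, 0.12) * kobs
  f1 <- fit_kobs_line(CE, kobs_n, sd)
  ord <- c(3, 1, 4, 2)
  f2 <- fit_kobs_line(CE[ord], kobs_n[ord], sd[ord])
  f3 <- fit_kobs_line(CE, kobs_n, 7 * sd)
  expect_equal(f1$kon, f2$kon, tolerance = 1e-12)
  expect_equal(f1$kon, f3$kon, tolerance = 1e-12)

  expect_error(fit_kobs_line(CE[1:2], kobs[1:2]), "3 distinct")
})

test_that("dissociation fit recovers koff and normalises correctly", {
  tt <- seq(0, 600, by = 30)
  p <- 0.9 * exp(-1.2e-2 * tt)
  s <- bound_fraction_series(tt, p, kind = "dissociation")
  fit <- fit_dissociation(s)
  expect_rel_equal(coef(fit)[["koff"]], 1.2e-2, 1e-8)
  expect_rel_equal(coef(fit)[["p0"]], 0.9, 1e-8)
  expect_equal(fit$normalized$p_norm[1L], 1, tolerance = 1e-8)

  ks <- vapply(1:20, function(i) {
    pn <- apply_noise(p, noise_spec(sigma = 0.02, seed = i))
    coef(fit_dissociation(bound_fraction_series(
      tt, pn, kind = "dissociation")))[["koff"]]
  }, numeric(1))
  expect_lt(abs(stats::median(ks) - 1.2e-2) / 1.2e-2, 0.10)
})

test_that("titration fit recovers Kd and detects unidentifiable designs", {
  CS <- 10e-9
  CE <- exp(seq(log(10e-9), log(10e-6), length.out = 12))
  p <- equilibrium_occupancy(CS, CE, 31e-9)
  fit <- fit_titration(CE, p, CS)
  expect_rel_equal(coef(fit)[["Kd"]], 31e-9, 1e-6)
  expect_true(fit$local_min_ok)

  expect_error(fit_titration(CE, rep(0.01, 12), CS), "unidentifiable")
  expect_error(fit_titration(CE, rep(0.97, 12), CS), "unidentifiable")

  kds <- vapply(1:20, function(i) {
    ti <- make_titration(0.031e-6, CS = CS,
                         noise = noise_spec(sigma = 0.03, seed = i))
    coef(fit_titration(ti$CE, ti$p, CS))[["Kd"]]
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 0.031e-6) / 0.031e-6, 0.15)
})

test_that("quadratic and hyperbolic isotherms converge as CS/Kd -> 0", {
  Kd <- 1e-7
  CE <- exp(seq(log(1e-9), log(1e-5), length.out = 14))
  rel_diff <- function(CS) {
    p <- equilibrium_occupancy(CS, CE, Kd)
    kd_quad <- coef(fit_titration(CE, p, CS))[["Kd"]]
    # independent hyperbolic (ligand-excess) fit
    hyp <- stats::optimize(function(kd) sum((CE / (CE + kd) - p)^2),
                           c(Kd / 20, 20 * Kd), tol = 1e-15)$minimum
    abs(kd_quad - hyp) / hyp
  }
  d_tenth <- rel_diff(0.1 * Kd)       # numerically ~0.047 on this grid
  d_hundredth <- rel_diff(0.01 * Kd)  # ~0.005
  expect_lt(d_tenth, 0.06)
  expect_lt(d_hundredth, 0.0075)
  expect_lt(d_hundredth, d_tenth / 5)   # ~linear shrinkage with CS/Kd
})

test_that("single-turnover fit reports the half-time", {
  tt <- seq(600, 36000, by = 600)
  f <- 1 - exp(-7.8e-5 * tt)
  fit <- fit_single_turnover(tt, f)
  expect_rel_equal(coef(fit)[["k"]], 7.8e-5, 1e-8)
  expect_equal(round(fit$t_half_min), 148)

  tt2 <- seq(0.1, 6, by = 0.1)
  fit2 <- fit_single_turnover(tt2, 1 - exp(-log(2) * tt2))
  expect_equal(fit2$t_half_s, 1, tolerance = 1e-8)
})

test_that("fold changes round by the reporting convention", {
  expect_equal(fold_change(0.9, 0.031, "integer"), 29)
  expect_equal(fold_change(6.4e-3, 0.45e-3, "integer"), 14)
  expect_equal(fold_change(12, 5, "one_decimal"), 2.4)
  expect_equal(fold_change(3, 3), 1)
  expect_error(fold_change(-1, 2), "positive")
  expect_error(fold_change(1, 0), "positive")
})
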