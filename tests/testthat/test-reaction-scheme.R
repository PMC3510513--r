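test_that("two-state decay matches the closed form and malformed schemes fail", {
  k <- 3e-3
  sc <- linear_scheme(c("A", "B"),
                      data.frame(from = "A", to = "B", rate = k),
                      init = c(A = 1, B = 0))
  tt <- c(10, 100, log(2) / k, 2000)
  sim <- simulate_linear_scheme(sc, tt)
  expect_lt(max(abs(sim$A - exp(-k * tt))), 1e-8)
  expect_equal(sim$A[3L], 0.5, tolerance = 1e-8)
  expect_lt(max(abs(sim$A + sim$B - 1)), 1e-8)

  expect_error(linear_scheme(c("A", "B"),
                             data.frame(from = "A", to = "B", rate = -1),
                             init = c(A = 1, B = 0)),
               "A -> B")
  expect_error(linear_scheme(c("A", "B"),
                             data.frame(from = "A", to = "C", rate = 1),
                             init = c(A = 1, B = 0)),
               "unknown state")
  expect_error(linear_scheme(c("A", "B"),
                             data.frame(from = "A", to = "B", rate = 1),
                             init = c(A = 0.7, B = 0.6)),
               "sum to 1")
})

test_that("with kcat = 0 the bound species decay independently", {
  rs <- rate_set(koff_S = 0.45e-3, kcat = 0, koff_P = 6.4e-3)
  sc <- scheme3_post_dilution(rs, 0.6, 0.3)
  tt <- c(50, 200, 1000, 4000)
  sim <- simulate_linear_scheme(sc, tt)
  expect_lt(max(abs(sim$ES - 0.6 * exp(-rs$koff_S * tt))), 1e-8)
  expect_lt(max(abs(sim$EP - 0.3 * exp(-rs$koff_P * tt))), 1e-8)
})

test_that("exact dilution response agrees with the ODE oracle", {
  rs <- coupled_truth()
  tt <- c(1e-6, 100, 1000, 5000)
  cf <- dilution_response(rs, 1, 0, tt)
  sim <- simulate_linear_scheme(scheme3_post_dilution(rs, 1, 0), tt)
  expect_lt(max(abs(sim$ES + sim$EP - cf$p_exact)), 1e-8)
  expect_false(cf$degenerate)

  # with no conversion the exact and approximate forms coincide
  rs0 <- rate_set(koff_S = 1.2e-2, kcat = 0, koff_P = 6.4e-3)
  cf0 <- dilution_response(rs0, 0.8, 0, tt)
  expect_equal(cf0$p_exact, 0.8 * exp(-1.2e-2 * tt), tolerance = 1e-12)
  expect_equal(cf0$max_dev, 0)
})

test_that("closed form matches the ODE oracle for random rate sets", {
  set.seed(11)
  tt <- c(5, 50, 500, 2000)
  for (i in 1:100) {
    k <- stats::runif(3, 1e-4, 2e-2)
    # keep eigenvalues distinct so the generic two-exponential branch is hit
    while (abs(k[3] - (k[1] + k[2])) < 1e-4) k[3] <- stats::runif(1, 1e-4, 2e-2)
    f <- stats::runif(2); f <- 0.9 * f / max(1, sum(f))
    rs <- rate_set(koff_S = k[1], kcat = k[2], koff_P = k[3])
    cf <- dilution_response(rs, f[1], f[2], tt)
    sim <- simulate_linear_scheme(scheme3_post_dilution(rs, f[1], f[2]), tt)
    expect_lt(max(abs(sim$ES + sim$EP - cf$p_exact)), 1e-8)
  }
})

test_that("degenerate rate equality switches to the confluent form", {
  rs <- rate_set(koff_S = 1e-3, kcat = 0.5e-3, koff_P = 1.5e-3)
  tt <- c(10, 300, 2000)
  cf <- dilution_response(rs, 0.7, 0.2, tt)
  expect_true(cf$degenerate)
  sim <- simulate_linear_scheme(scheme3_post_dilution(rs, 0.7, 0.2), tt)
  expect_lt(max(abs(sim$ES + sim$EP - cf$p_exact)), 1e-8)
})

test_that("two-term reading deviates little when conversion is slow", {
  rs <- coupled_truth()   # kcat << koff_P - koff_S - kcat
  tt <- seq(0, 90 * 60, by = 30)
  cf <- dilution_response(rs, 1, 0, tt)
  # numerically scanned bound, small relative to p(0) = 1
  expect_equal(cf$max_dev, max(abs(cf$p_exact - cf$p_approx)))
  expect_lt(cf$max_dev, 0.05)
  expect_gt(cf$max_dev, 0)
})

test_that("pre-dilution composition is exact mass action", {
  expect_equal(pre_dilution_state(2e-6, 6e-6, 0.32e-6, 0.19e-3, 0),
               c(fS0 = 1, fP0_bound = 0, fP0_free = 0))

  # fully converted limit: bound product fraction is the equilibrium
  # occupancy of the product at (CS, CE, Kd_P)
  st_inf <- pre_dilution_state(2e-6, 6e-6, 0.32e-6, 0.19e-3, 1e9)
  expect_equal(st_inf[["fS0"]], 0)
  expect_equal(st_inf[["fP0_bound"]],
               equilibrium_occupancy(2e-6, 6e-6, 0.32e-6), tolerance = 1e-10)

  # quadratic vs bisection oracle at the 62-minute design point
  st <- pre_dilution_state(2e-6, 6e-6, 0.32e-6, 0.19e-3, 62 * 60)
  fS <- exp(-0.19e-3 * 62 * 60)
  B <- bisect_product_bound(6e-6 - 2e-6 * fS, 2e-6 * (1 - fS), 0.32e-6)
  expect_equal(st[["fP0_bound"]], B / 2e-6, tolerance = 1e-10)
  expect_equal(sum(st), 1, tolerance = 1e-12)
})

test_that("quadratic isotherm matches the bisection oracle and its limits", {
  expect_equal(equilibrium_occupancy(10e-9, 0, 31e-9), 0)
  # stoichiometric limit Kd = 0
  expect_equal(equilibrium_occupancy(10e-9, 4e-9, 0), 0.4, tolerance = 1e-12)
  expect_equal(equilibrium_occupancy(10e-9, 40e-9, 0), 1, tolerance = 1e-12)

  expect_equal(equilibrium_occupancy(10e-9, 31e-9, 31e-9),
               bisect_occupancy(10e-9, 31e-9, 31e-9), tolerance = 1e-10)
  grid <- expand.grid(CS = 10^seq(-9, -5), CE = 10^seq(-9, -5),
                      Kd = 10^seq(-9, -5))
  p_pkg <- mapply(equilibrium_occupancy, grid$CS, grid$CE, grid$Kd)
  p_ora <- mapply(bisect_occupancy, grid$CS, grid$CE, grid$Kd)
  expect_lt(max(abs(p_pkg - p_ora)), 1e-10)

  # monotone nondecreasing in CE, nonincreasing in Kd
  CE <- 10^seq(-9, -5, length.out = 40)
  expect_true(all(diff(equilibrium_occupancy(10e-9, CE, 31e-9)) >= 0))
  Kds <- 10^seq(-9, -5, length.out = 40)
  pK <- vapply(Kds, function(kd) equilibrium_occupancy(10e-9, 1e-7, kd),
               numeric(1))
  expect_true(all(diff(pK) <= 0))

  # hyperbolic limit law when CS << Kd
  Kd <- 1e-7; CS <- Kd / 100
  p <- equilibrium_occupancy(CS, CE, Kd)
  expect_lt(max(abs(p - CE / (CE + Kd)) / (CE / (CE + Kd))), 0.01)
})

test_that("association simulation converges to equilibrium and conserves mass", {
  tt <- seq(1, 4000, by = 20)
  # irreversible binding at enzyme excess saturates
  tr <- simulate_association(10e-9, 1e-6, 2.7e4, 0, tt)
  expect_gt(tail(tr$p, 1), 0.999)
  tr0 <- simulate_association(10e-9, 0.5e-6, 2.7e4, 1.2e-2, c(0, 10, 100))
  expect_equal(tr0$p[1L], 0)

  # long-time limit equals the quadratic isotherm
  tr2 <- simulate_association(10e-9, 0.5e-6, 2.7e4, 1.2e-2, c(100, 5e4))
  expect_equal(tail(tr2$p, 1),
               equilibrium_occupancy(10e-9, 0.5e-6, 1.2e-2 / 2.7e4),
               tolerance = 1e-7)

  # mass conservation on the full mass-action chase
  rs <- coupled_truth()
  rs$kon <- 2.7e4
  sim <- simulate_dilution(rs, 0.5e-9, 1.5e-9, 0.5, 0.45, 0.03,
                           times = seq(10, 5000, by = 100),
                           reassociation = TRUE)
  rna <- sim$S + sim$ES + sim$EP + sim$P
  enz <- sim$E_free + sim$ES + sim$EP
  expect_lt(max(abs(rna / rna[1L] - 1)), 1e-8)
  expect_lt(max(abs(enz / enz[1L] - 1)), 1e-8)
})
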