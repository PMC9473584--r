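# Free-energy functionals and the self-consistent internal state.

test_that("reference mixing free energy matches hand evaluation and limits", {
  p <- fus_pure()
  # (0.5/526) log 0.5 + (0.5/65) log 0.5
  expect_equal(f_reference(0.5, p), -5.991e-3, tolerance = 1e-4)
  expect_equal(f_reference(0, p), 0)
  expect_equal(f_reference(1, p), 0)
  expect_error(f_reference(1.2, p), "phi")
})

test_that("pure bond fraction satisfies mass action and direct minimization", {
  p <- fus_pure()
  for (phi in c(1e-4, 0.01, 0.1, 0.5, 0.9)) {
    pv <- solve_p_pure(phi, p)
    K <- (p$protein$m2 * phi / p$protein$N1) * exp(-p$beta_eps1)
    resid <- pv / ((1 - pv) * (1 - pv * p$protein$m1 / p$protein$m2)) - K
    expect_lt(abs(resid), 1e-12)
    # agreement with direct 1-D minimization of the binding free energy
    opt <- optimize(function(x) f_binding_pure(phi, x, p),
                    c(1e-12, 1 - 1e-12), tol = 1e-12)
    expect_equal(pv, opt$minimum, tolerance = 1e-6)
  }
  expect_equal(solve_p_pure(0, p), 0)
  # example value at phi = 0.1, beta_eps1 = -2
  expect_equal(solve_p_pure(0.1, p), 0.0436, tolerance = 2e-3)
})

test_that("binding free energy vanishes without bonds and guards its domain", {
  p <- fus_pure()
  expect_equal(f_binding_pure(0.3, 0, p), 0)
  expect_error(f_binding_pure(0.3, 1.2, p), "budget")
  asym <- model_params(protein_spec(100, 20, 10))
  expect_error(f_binding_pure(0.3, 0.9, asym), "budget")  # p m1/m2 = 1.8
})

test_that("reservoir chemical potential matches its printed form", {
  p <- fus_profile("fus2022")
  expect_equal(mu_atp_reservoir(0.1, p), -2.2763485, tolerance = 1e-6)
  ideal <- model_params(protein_spec(10, 1, 1), N2 = 1, chi = 0)
  expect_equal(mu_atp_reservoir(0.5, ideal), 0)
  grid <- seq(0.01, 0.39, by = 0.02)
  expect_true(all(diff(mu_atp_reservoir(grid, p)) > 0))
  expect_error(mu_atp_reservoir(0, p))
  expect_error(mu_atp_reservoir(1, p))
})

test_that("ATP reference free energy reduces to the pure model at lam = 0", {
  p <- fus_profile("fus2022", atp_reservoir_phi = 0.05)
  for (phi in c(0.01, 0.1, 0.4))
    expect_equal(f_reference_atp(phi, 0, p), f_reference(phi, p))
  # term-by-term hand assembly at phi = 0.1, lam = 0.5
  phi <- 0.1; lam <- 0.5
  mub <- mu_atp_reservoir(0.05, p)
  S <- 1 - phi - lam * phi
  byhand <- phi / 526 * log(phi) + S / 65 * log(S) +
    lam * phi * log(lam * phi) + (-1.2) * lam * phi * S - lam * phi * mub
  expect_equal(f_reference_atp(phi, lam, p), byhand, tolerance = 1e-12)
  expect_error(f_reference_atp(0.5, 1.2, p), "exceed")
})

test_that("coupled binding free energy decouples and vanishes correctly", {
  p <- fus_profile("fus2022", atp_reservoir_phi = 0.01)
  pure <- fus_pure()
  for (phi in c(0.05, 0.3)) {
    pv <- solve_p_pure(phi, pure)
    expect_equal(f_binding_atp(phi, 0, pv, 0, p),
                 f_binding_pure(phi, pv, pure))
  }
  expect_equal(f_binding_atp(0.2, 0.1, 0, 0, p), 0)
  expect_error(f_binding_atp(0.2, 0.5, 0.9, 0.9, p), "budget")
})

test_that("internal state solves the joint stationarity conditions", {
  p <- fus_profile("fus2022", L = 2, atp_reservoir_phi = 1e-3)
  for (phi in c(0.01, 0.1, 0.4)) {
    st <- solve_internal(phi, p)
    # constraint slack
    t <- st$p * 34 / 34 + st$q * 2 * st$lam * 526 / 34
    expect_gte(1 - t, 0)
    expect_gt(1 - phi - st$lam * phi, 0)
    # stationarity via central differences of the explicit functional
    h <- 1e-7
    dp <- (f_at_state(phi, st$lam, st$p + h, st$q, p) -
           f_at_state(phi, st$lam, st$p - h, st$q, p)) / (2 * h)
    dq <- (f_at_state(phi, st$lam, st$p, st$q + h, p) -
           f_at_state(phi, st$lam, st$p, st$q - h, p)) / (2 * h)
    dl <- (f_at_state(phi, st$lam + h, st$p, st$q, p) -
           f_at_state(phi, st$lam - h, st$p, st$q, p)) / (2 * h)
    expect_lt(abs(dp), 1e-5)
    expect_lt(abs(dq), 1e-5)
    expect_lt(abs(dl), 1e-5)
    # local minimum: positive-definite numeric Hessian in (p, q, lam)
    x0 <- c(st$p, st$q, st$lam)
    fx <- function(x) f_at_state(phi, x[3], x[1], x[2], p)
    H <- matrix(0, 3, 3)
    hh <- 1e-5
    for (i in 1:3) for (j in 1:3) {
      ei <- ej <- numeric(3); ei[i] <- hh; ej[j] <- hh
      H[i, j] <- (fx(x0 + ei + ej) - fx(x0 + ei - ej) -
                  fx(x0 - ei + ej) + fx(x0 - ei - ej)) / (4 * hh^2)
    }
    expect_true(all(eigen(0.5 * (H + t(H)))$values > 0))
  }
})

test_that("internal state recovers its limits", {
  # empty reservoir: pure-solution order parameters
  p0 <- fus_pure()
  st <- solve_internal(0.2, p0)
  expect_equal(st$q, 0)
  expect_equal(st$lam, 0)
  expect_equal(st$p, solve_p_pure(0.2, p0))
  # vanishing reservoir approaches the pure limit continuously
  peps <- fus_profile("fus2022", atp_reservoir_phi = 1e-12)
  st2 <- solve_internal(0.2, peps)
  expect_equal(st2$p, solve_p_pure(0.2, p0), tolerance = 1e-6)
  expect_lt(st2$lam, 1e-8)
  # ATP binding switched off: q -> 0 at any reservoir level
  poff <- fus_profile("fus2022", beta_eps2 = 60, atp_reservoir_phi = 0.01)
  expect_lt(solve_internal(0.2, poff)$q, 1e-10)
})

test_that("bound Arg per ATP is larger for the bivalent binder when ATP is scarce", {
  c_low <- 1e-5
  g <- sapply(1:2, function(L) {
    p <- fus_profile("fus2022", L = L, beta_eps2 = -8,
                     atp_reservoir_phi = molar_to_phi(c_low))
    L * solve_internal(0.1, p)$q
  })
  expect_gt(g[2], g[1])
})

test_that("total free energy is consistent, smooth, and obeys the envelope", {
  p <- fus_profile("fus2022", L = 2, atp_reservoir_phi = 5e-4)
  p0 <- fus_pure()
  # ATP-free consistency of the two model variants
  ft <- f_total(0.15, p0)
  expect_equal(ft$f,
               f_reference(0.15, p0) +
                 f_binding_pure(0.15, solve_p_pure(0.15, p0), p0),
               tolerance = 1e-12)
  # envelope: numerical total derivative equals the analytic mu
  for (phi in c(0.01, 0.08, 0.3, 0.6)) {
    h <- phi * 1e-6
    num <- (f_total(phi + h, p)$f - f_total(phi - h, p)$f) / (2 * h)
    mu <- mu_and_pressure(phi, p)$mu
    expect_equal(num, mu, tolerance = 1e-6)
  }
  # smoothness along the composition grid
  grid <- exp(seq(log(1e-6), log(0.9), length.out = 120))
  fv <- vapply(grid, function(x) f_total(x, p)$f, 0)
  expect_true(all(is.finite(fv)))
  expect_lt(max(abs(diff(fv, differences = 2))), 1e-2)
})
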