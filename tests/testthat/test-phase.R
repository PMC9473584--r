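# Spinodal, binodal and tie-line machinery.

test_that("convex free energy yields no spinodal and no coexistence", {
  p <- fus_pure(beta_eps1 = 5)   # binding switched off
  expect_length(spinodal_interval(p), 0)
  cx <- solve_coexistence(p)
  expect_false(cx$converged)
  # mu globally increasing
  grid <- exp(seq(log(1e-6), log(0.9), length.out = 60))
  mus <- vapply(grid, function(x) mu_and_pressure(x, p)$mu, 0)
  expect_true(all(diff(mus) > 0))
})

test_that("reference tie-line satisfies equal mu/Pi and the common tangent", {
  p <- fus_pure()
  sp <- spinodal_interval(p)
  expect_length(sp, 2)
  cx <- solve_coexistence(p)
  expect_true(cx$converged)
  expect_false(cx$clipped)
  # spinodal strictly inside the binodal
  expect_lt(cx$phi_dilute, sp[1])
  expect_gt(cx$phi_dense, sp[2])
  # equal chemical potential and osmotic pressure
  expect_lt(cx$residual_mu, 1e-8)
  expect_lt(cx$residual_Pi, 1e-8)
  r1 <- mu_and_pressure(cx$phi_dilute, p)
  r2 <- mu_and_pressure(cx$phi_dense, p)
  # Legendre consistency of the reported state
  expect_equal(r1$Pi, cx$phi_dilute * r1$mu - r1$f, tolerance = 1e-10)
  # common tangent: f lies on or above the tangent between the phases
  lam <- seq(0.02, 0.98, by = 0.04)
  phis <- cx$phi_dilute + lam * (cx$phi_dense - cx$phi_dilute)
  fline <- r1$f + (phis - cx$phi_dilute) * cx$mu
  fvals <- vapply(phis, function(x) f_total(x, p)$f, 0)
  expect_true(all(fvals >= fline - 1e-10))
  # dense phase is more cross-linked than the dilute phase
  expect_gt(cx$p_dense, cx$p_dilute)
})

test_that("tie-line is stable under solver-resolution perturbations", {
  p <- fus_pure()
  a <- solve_coexistence(p, n_grid = 200, phi_max = 0.96)
  b <- solve_coexistence(p, n_grid = 320, phi_max = 0.98)
  expect_equal(a$phi_dilute, b$phi_dilute, tolerance = 1e-8)
  expect_equal(a$phi_dense, b$phi_dense, tolerance = 1e-8)
})

test_that("critical point brackets the appearance of coexistence", {
  p <- fus_pure()
  cp <- critical_point(p, "beta_eps1", bracket = c(-2, -1))
  expect_gt(cp$value, -1.5)
  expect_lt(cp$value, -1.3)
  expect_true(is.finite(cp$phi_c))
  # binodal width shrinks toward the critical point
  w <- sapply(cp$value - c(0.15, 0.05), function(e) {
    cx <- solve_coexistence(fus_pure(beta_eps1 = e))
    cx$phi_dense - cx$phi_dilute
  })
  expect_lt(w[2], w[1])
  # spinodal encloses the critical composition just inside coexistence
  sp <- spinodal_interval(fus_pure(beta_eps1 = cp$value - 0.05))
  expect_gte(cp$phi_c, sp[1] * 0.5)
  expect_lte(cp$phi_c, sp[2] * 2)
  expect_error(critical_point(p, "beta_eps1", bracket = c(-3, -2.5)),
               "straddle")
})

test_that("deeply driven tie-lines report a clipped dilute branch", {
  # strong ATP crosslinking drives the formal dilute branch below any
  # representable composition; the solver must flag, not fail
  p <- fus_profile("fus2022", L = 2, beta_eps2 = -8,
                   atp_reservoir_phi = molar_to_phi(3e-4))
  cx <- solve_coexistence(p)
  expect_true(cx$converged)
  expect_true(cx$clipped)
  expect_true(is.finite(cx$rho_dense))
  expect_lte(cx$phi_dilute, 1e-12)
})

test_that("dissolution search validates its bracket", {
  p <- fus_profile("fus2022", L = 2)
  expect_error(dissolution_concentration(p, c_bracket = c(1e-8, 2e-8)),
               "persists")
  expect_error(
    dissolution_concentration(fus_profile("asym_hiY"),
                              c_bracket = c(1e-9, 0.2)),
    "lower end")   # asymmetric protein does not phase separate without ATP
})
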