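# Phase equilibrium: chemical potential / osmotic pressure, spinodal,
# binodal (tie-lines), critical points, dissolution, and scans.

#' Exchange chemical potential and osmotic pressure of the protein
#'
#' `mu = d f_total / d phi` computed analytically through the envelope
#' theorem (the internal optimum makes all implicit derivatives
#' vanish), and `Pi = phi * mu - f_total`.  Two coexisting phases have
#' equal mu and equal Pi.
#'
#' @inheritParams solve_internal
#' @return A list with `mu`, `Pi`, `f` and `state`.
#' @export
mu_and_pressure <- function(phi, params) {
  stopifnot(inherits(params, "model_params"))
  if (length(phi) != 1 || phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)")
  st <- .solve_internal_state(phi, params)
  .mu_pi_at(phi, st, params)
}

.mu_pi_at <- function(phi, st, params) {
  pr <- params$protein
  lam <- st$lam; lamphi <- st$lamphi; S <- st$S
  mub <- if (params$atp_reservoir_phi > 0)
    mu_atp_reservoir(params$atp_reservoir_phi, params) else 0
  atp_mix <- if (lam > 0) lam * (log(lamphi) + 1) else 0
  dref <- (log(phi) + 1) / pr$N1 -
    (lam + 1) / params$N2 * (log(S) + 1) + atp_mix +
    params$chi * lam * (1 - 2 * phi - 2 * lamphi) - lam * mub
  fb <- .f_bind_at(phi, st, params)
  mu <- dref + fb / phi - (st$p * pr$m1 / pr$N1 + st$q * params$L * lam)
  f <- .f_total_at(phi, st, params)
  list(mu = mu, Pi = phi * mu - f, f = f, state = st)
}

# chemical potential only (hot path)
.mu_at <- function(phi, params) .mu_pi_at(phi, .solve_internal_state(phi, params), params)$mu

# log-spaced composition grid used by the stability scans
.phi_grid <- function(n, phi_min = 1e-8, phi_max = 0.95)
  exp(seq(log(phi_min), log(phi_max), length.out = n))

# TRUE when the free energy has a concave window (mu decreasing
# somewhere), i.e. when a two-phase region exists
.has_coexistence <- function(params, n_grid = 160, phi_max = 0.95) {
  phis <- .phi_grid(n_grid, phi_max = phi_max)
  mus <- vapply(phis, .mu_at, 0, params = params)
  any(diff(mus) < 0)
}

#' Spinodal interval of the protein volume fraction
#'
#' Locates the zeros of the free-energy curvature `d mu / d phi` by a
#' sign scan on a log-spaced grid followed by bracketed root
#' refinement.  Empty when the free energy is convex (no phase
#' separation).
#'
#' @param params a [model_params()].
#' @param n_grid scan resolution.
#' @param phi_max upper end of the scanned composition range.
#' @return Numeric vector of spinodal compositions (usually length 0
#'   or 2, sorted).
#' @export
spinodal_interval <- function(params, n_grid = 220, phi_max = 0.95) {
  stopifnot(inherits(params, "model_params"))
  phis <- .phi_grid(n_grid, phi_max = phi_max)
  mus <- vapply(phis, .mu_at, 0, params = params)
  s <- sign(diff(mus))
  flips <- which(s[-1] * s[-length(s)] < 0)
  if (!any(s < 0)) return(numeric(0))
  dmu <- function(phi) {
    h <- phi * 1e-6
    (.mu_at(phi + h, params) - .mu_at(phi - h, params)) / (2 * h)
  }
  roots <- vapply(flips, function(i) {
    lo <- phis[i]; hi <- phis[i + 2]
    if (dmu(lo) * dmu(hi) > 0) return(NA_real_)
    uniroot(dmu, c(lo, hi), tol = 1e-12)$root
  }, 0)
  sort(roots[is.finite(roots)])
}

#' Solve the two-phase coexistence (one tie-line)
#'
#' Finds the dilute/dense pair with equal protein chemical potential
#' and equal osmotic pressure by the equal-grand-potential
#' construction: for a trial mu the two outer roots of
#' `mu(phi) = mu` are located on either side of the spinodal, and mu is
#' adjusted until their grand potentials `f - mu phi` agree (equivalent
#' to equal Pi, and to the common-tangent construction).  The bracket
#' in mu is `(mu(phi_s2), mu(phi_s1))`, where the objective is strictly
#' monotone, so the tie-line is found without initial guesses.
#'
#' @param params a [model_params()].
#' @param n_grid resolution of the stability scan.
#' @param phi_max upper end of the composition range searched.
#' @param phi_floor smallest representable dilute composition.  The
#'   chemical potential diverges only like `log(phi)/N1`, so deep in a
#'   strongly driven two-phase region the formal dilute branch can lie
#'   at compositions far below one chain per macroscopic volume; when
#'   the equilibrium `mu` falls below `mu(phi_floor)` the dilute
#'   branch is reported clamped at the floor with `clipped = TRUE`.
#' @return A list of class `coexistence_result`:
#'   `phi_dilute`, `phi_dense`, chain molarities `rho_dilute`,
#'   `rho_dense` (mol/L), bond fractions `p_dilute`, `p_dense`,
#'   ATP-site occupancy `q_dense`, bound Arg per ATP
#'   `g_dense = L q_dense`, `mu`, `Pi`, residuals, a `clipped` flag
#'   and a `converged` flag.  `converged = FALSE` with NA fields when
#'   no two-phase region exists.
#' @export
solve_coexistence <- function(params, n_grid = 260, phi_max = 0.97,
                              phi_floor = 1e-13) {
  stopifnot(inherits(params, "model_params"))
  no_coex <- structure(list(converged = FALSE, clipped = FALSE,
                            phi_dilute = NA_real_, phi_dense = NA_real_,
                            rho_dilute = NA_real_, rho_dense = NA_real_,
                            p_dilute = NA_real_, p_dense = NA_real_,
                            q_dense = NA_real_, g_dense = NA_real_,
                            mu = NA_real_, Pi = NA_real_,
                            residual_mu = NA_real_, residual_Pi = NA_real_),
                       class = "coexistence_result")
  sp <- spinodal_interval(params, n_grid = n_grid, phi_max = phi_max)
  if (length(sp) < 2) return(no_coex)
  phi_s1 <- sp[1]; phi_s2 <- sp[length(sp)]
  mu_hi <- .mu_at(phi_s1, params)   # local max of mu
  mu_lo <- .mu_at(phi_s2, params)   # local min of mu
  if (!(mu_lo < mu_hi)) return(no_coex)
  # make sure the dense branch reaches above mu_hi
  top <- phi_max
  while (.mu_at(top, params) < mu_hi && top < 0.9995)
    top <- top + (1 - top) / 2
  mu_cap <- min(mu_hi, .mu_at(top, params))
  mu_floor <- .mu_at(phi_floor, params)
  omega <- function(phi, mu) {
    st <- .solve_internal_state(phi, params)
    .f_total_at(phi, st, params) - mu * phi
  }
  dilute_root <- function(mu)
    uniroot(function(x) .mu_at(x, params) - mu,
            c(phi_floor, phi_s1), tol = 1e-15)$root
  dense_root <- function(mu)
    uniroot(function(x) .mu_at(x, params) - mu,
            c(phi_s2, top), tol = 1e-15)$root
  gap <- function(mu) {
    b1 <- dilute_root(mu); b2 <- dense_root(mu)
    omega(b1, mu) - omega(b2, mu)
  }
  eps <- (mu_hi - mu_lo) * 1e-10
  lo_end <- max(mu_lo, mu_floor) + eps
  hi_end <- mu_cap - eps
  if (!(lo_end < hi_end)) return(no_coex)
  g_hi <- gap(hi_end)
  if (!is.finite(g_hi) || g_hi < 0) return(no_coex)  # dense branch clipped
  g_lo <- gap(lo_end)
  clipped <- FALSE
  if (!is.finite(g_lo)) return(no_coex)
  if (g_lo >= 0) {
    # equilibrium mu below mu(phi_floor): dilute branch under the floor
    clipped <- TRUE
    mu_star <- lo_end
    b <- c(phi_floor, dense_root(mu_star))
  } else {
    mu_star <- uniroot(gap, c(lo_end, hi_end), tol = 1e-15)$root
    b <- c(dilute_root(mu_star), dense_root(mu_star))
  }
  r1 <- .mu_pi_at(b[1], .solve_internal_state(b[1], params), params)
  r2 <- .mu_pi_at(b[2], .solve_internal_state(b[2], params), params)
  N1 <- params$protein$N1
  structure(list(converged = TRUE, clipped = clipped,
                 phi_dilute = b[1], phi_dense = b[2],
                 rho_dilute = phi_to_molar(b[1], N1, params$residue_size_nm),
                 rho_dense = phi_to_molar(b[2], N1, params$residue_size_nm),
                 p_dilute = r1$state$p, p_dense = r2$state$p,
                 q_dense = r2$state$q,
                 g_dense = params$L * r2$state$q,
                 mu = mu_star, Pi = (r1$Pi + r2$Pi) / 2,
                 residual_mu = if (clipped) NA_real_ else abs(r1$mu - r2$mu),
                 residual_Pi = if (clipped) NA_real_ else abs(r1$Pi - r2$Pi)),
            class = "coexistence_result")
}

#' @export
print.coexistence_result <- function(x, ...) {
  if (!x$converged) {
    cat("<coexistence_result> no two-phase region\n")
  } else {
    cat(sprintf(paste0("<coexistence_result> phi1 = %.4g, phi2 = %.4g | ",
                       "rho1 = %.4g M, rho2 = %.4g M | p2 = %.3g\n"),
                x$phi_dilute, x$phi_dense, x$rho_dilute, x$rho_dense,
                x$p_dense))
  }
  invisible(x)
}

#' Locate the critical point along a scan axis
#'
#' Bisects the appearance/disappearance of the two-phase region along
#' either the Tyr-Arg binding energy or the reservoir ATP concentration
#' and reports the threshold together with the critical composition
#' (the collapsing spinodal midpoint).
#'
#' @param params a [model_params()].
#' @param scan_axis `"beta_eps1"` or `"atp_concentration"`.
#' @param bracket length-2 numeric: scan values with and without
#'   coexistence (kT for `beta_eps1`, mol/L for `atp_concentration`).
#' @param rel_tol relative tolerance on the scan value.
#' @return A list with `value` (threshold on the scan axis), `phi_c`
#'   (critical composition estimate) and the axis name.
#' @export
critical_point <- function(params,
                           scan_axis = c("beta_eps1", "atp_concentration"),
                           bracket, rel_tol = 1e-4) {
  stopifnot(inherits(params, "model_params"), length(bracket) == 2)
  scan_axis <- match.arg(scan_axis)
  with_value <- function(x) {
    if (scan_axis == "beta_eps1") params$beta_eps1 <- x
    else params$atp_reservoir_phi <- molar_to_phi(x, 1, params$residue_size_nm)
    params
  }
  ex <- function(x) .has_coexistence(with_value(x))
  lo <- bracket[1]; hi <- bracket[2]
  e_lo <- ex(lo); e_hi <- ex(hi)
  if (e_lo == e_hi)
    stop("bracket does not straddle the onset of coexistence")
  while (abs(hi - lo) > rel_tol * max(abs(lo), abs(hi), 1e-12)) {
    mid <- (lo + hi) / 2
    if (ex(mid) == e_lo) lo <- mid else hi <- mid
  }
  value <- (lo + hi) / 2
  inside <- if (e_lo) lo else hi
  sp <- spinodal_interval(with_value(inside))
  phi_c <- if (length(sp) >= 2) mean(c(sp[1], sp[length(sp)])) else NA_real_
  list(axis = scan_axis, value = value, phi_c = phi_c)
}

#' Reservoir ATP concentration that dissolves the condensate
#'
#' The smallest reservoir ATP concentration at which no two compositions
#' coexist (binodal loop closure), located by bisection in log
#' concentration between a coexisting and a non-coexisting value.
#'
#' @param params a [model_params()]; coexistence must exist in the
#'   ATP-free limit.
#' @param c_bracket search bracket in mol/L.  The default upper end
#'   stays below reservoir fractions where the semi-grand model leaves
#'   its physical regime (the box floods with ATP).
#' @param rel_tol relative tolerance on the concentration.
#' @return Closure concentration in mol/L.
#' @export
dissolution_concentration <- function(params, c_bracket = c(1e-8, 0.2),
                                      rel_tol = 1e-3) {
  stopifnot(inherits(params, "model_params"))
  at_c <- function(cc) {
    params$atp_reservoir_phi <- molar_to_phi(cc, 1, params$residue_size_nm)
    .has_coexistence(params)
  }
  lo <- c_bracket[1]; hi <- c_bracket[2]
  if (!at_c(lo))
    stop("no coexistence at the lower end of the bracket")
  # back the upper end away from the unphysical high-reservoir regime
  while (at_c(hi) && hi > 20 * lo) hi <- hi / 1.6
  if (at_c(hi))
    stop("coexistence persists across the whole search bracket")
  while (hi / lo - 1 > rel_tol) {
    mid <- sqrt(lo * hi)
    if (at_c(mid)) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Onset of phase separation along the Tyr-Arg binding energy
#'
#' Largest (least negative) `beta_eps1` at which a two-phase region
#' exists, found by a coarse grid scan plus bisection.
#'
#' @param params a [model_params()] (ATP-free by default).
#' @param eps1_range scanned interval in kT.
#' @param grid_step resolution of the initial scan.
#' @param rel_tol bisection tolerance.
#' @return Threshold binding energy in kT.
#' @export
phase_separation_onset <- function(params, eps1_range = c(-3, -1),
                                   grid_step = 0.02, rel_tol = 1e-4) {
  stopifnot(inherits(params, "model_params"))
  ex <- function(e) { params$beta_eps1 <- e; .has_coexistence(params) }
  grid <- seq(eps1_range[1], eps1_range[2], by = grid_step)
  ok <- vapply(grid, ex, TRUE)
  if (!ok[1]) stop("no coexistence at the strong-binding end of the range")
  if (all(ok)) stop("coexistence everywhere in the scanned range")
  i <- max(which(ok))
  lo <- grid[i]; hi <- grid[i + 1]
  while (abs(hi - lo) > rel_tol) {
    mid <- (lo + hi) / 2
    if (ex(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
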