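# Mean-field free energies of the sticker-and-spacer model.
#
# All free energies are densities per lattice site (per residue volume
# v) in units of kT.  Internal order parameters:
#   p   fraction of Tyr engaged in Tyr-Arg bonds
#   q   fraction of ATP binding sites occupied by Arg
#   lam ATP molecules per protein residue, lambda = n_ATP/(n_p N1)
# The Arg budget couples them through
#   t = p m1/m2 + q L lam N1/m2   (fraction of Arg residues bound).

# x*log(x) with the exact 0 limit
.xlx <- function(x) ifelse(x > 0, x * log(x), 0)

#' Mixing free energy of the protein/solvent reference state
#'
#' Flory-Huggins entropy of a protein of length N1 mixed with solvent
#' chains of length N2 (no binding):
#' `(phi/N1) log(phi) + ((1-phi)/N2) log(1-phi)`.
#'
#' @param phi protein volume fraction in \[0, 1\]; the exact limit value
#'   0 is returned at both endpoints.
#' @param params a [model_params()].
#' @return Dimensionless free energy density (kT per site).
#' @export
f_reference <- function(phi, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]")
  .xlx(phi) / params$protein$N1 + .xlx(1 - phi) / params$N2
}

# mass-action equilibrium constants at a given phi
.Kconst <- function(phi, params) {
  pr <- params$protein
  base <- pr$m2 * phi / pr$N1
  list(K1 = base * exp(-params$beta_eps1),
       K2 = base * exp(-params$beta_eps2))
}

#' Tyr-Arg binding free energy of the ATP-free model
#'
#' Stirling form of `-(v/V) log Z` for the one-to-one Tyr-Arg
#' association: Tyr bond-fraction entropy, free-Arg entropy, and the
#' bond attachment term
#' `-(p m1 phi/N1) [log(m2 phi/N1) - beta_eps1 - 1]`
#' (the trailing -1 is the Euler factor from Stirling's approximation
#' of the bond-permutation factorial; see the methods vignette and
#' [exact_association_oracle()], which arbitrates the form).
#'
#' @param phi protein volume fraction in (0, 1).
#' @param p fraction of Tyr residues in Tyr-Arg bonds; must satisfy
#'   `p*m1/m2 < 1`.
#' @param params a [model_params()].
#' @return Dimensionless free energy density.
#' @export
f_binding_pure <- function(phi, p, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(phi <= 0 | phi >= 1)) stop("phi must lie in (0, 1)")
  pr <- params$protein
  if (pr$m1 == 0 || pr$m2 == 0) return(rep(0, length(phi)))
  if (any(p < 0 | p > 1 | 1 - p * pr$m1 / pr$m2 < 0))
    stop("p outside the feasible Arg budget")
  (pr$m1 * phi / pr$N1) * (.xlx(p) + .xlx(1 - p)) +
    (pr$m2 * phi / pr$N1) * .xlx(1 - p * pr$m1 / pr$m2) -
    (p * pr$m1 * phi / pr$N1) *
      (log(pr$m2 * phi / pr$N1) - params$beta_eps1 - 1)
}

#' Equilibrium Tyr-Arg bond fraction of the ATP-free model
#'
#' Closed-form root of the mass-action relation
#' `p / ((1-p)(1 - p m1/m2)) = (m2 phi / N1) exp(-beta_eps1)`,
#' the stationarity condition of [f_binding_pure()] in p.
#'
#' @inheritParams f_binding_pure
#' @return The bond fraction p in \[0, min(1, m2/m1)).
#' @export
solve_p_pure <- function(phi, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(phi < 0 | phi >= 1)) stop("phi must lie in [0, 1)")
  pr <- params$protein
  if (pr$m1 == 0 || pr$m2 == 0) return(rep(0, length(phi)))
  K <- pr$m2 * phi / pr$N1 * exp(-params$beta_eps1)
  r <- pr$m1 / pr$m2
  b <- 1 + K * (1 + r)
  # smaller root of K r p^2 - b p + K = 0, numerically stable form
  ifelse(K == 0, 0, 2 * K / (b + sqrt(b^2 - 4 * K^2 * r)))
}

#' Chemical potential of the ATP reservoir
#'
#' `mu_ATP = log(phibar) - log(1-phibar)/N2 - 1/N2 + 1 + chi (1-2 phibar)`
#' for a reservoir that is a binary ATP/solvent solution at ATP volume
#' fraction `phibar`.
#'
#' @param phi_bar reservoir ATP volume fraction in (0, 1).
#' @param params a [model_params()] (supplies N2 and chi).
#' @return Dimensionless chemical potential (kT).
#' @export
mu_atp_reservoir <- function(phi_bar, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(phi_bar <= 0 | phi_bar >= 1)) stop("phi_bar must lie in (0, 1)")
  log(phi_bar) - log(1 - phi_bar) / params$N2 - 1 / params$N2 + 1 +
    params$chi * (1 - 2 * phi_bar)
}

#' Reference free energy of the protein/solvent/ATP solution
#'
#' Mixing entropy of the three components plus the ATP-solvent contact
#' term and the reservoir-exchange term `-lam*phi*mu_ATP` that opens
#' the system to ATP (semi-grand ensemble):
#' protein `phi/N1 log phi`, solvent `(S/N2) log S` with
#' `S = 1 - phi - lam*phi`, ATP `lam*phi log(lam*phi)`,
#' contact `chi * lam*phi * S`.
#'
#' @param phi protein volume fraction in (0, 1).
#' @param lam ATP-per-residue loading, `n_ATP / (n_p N1)`; requires
#'   `phi (1 + lam) < 1`.
#' @param params a [model_params()] with `atp_reservoir_phi > 0`.
#' @return Dimensionless free energy density.
#' @export
f_reference_atp <- function(phi, lam, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(phi <= 0 | phi >= 1)) stop("phi must lie in (0, 1)")
  if (any(lam < 0)) stop("lam must be >= 0")
  S <- 1 - phi - lam * phi
  if (any(S <= 0)) stop("protein + ATP volume fractions exceed the box")
  mub <- if (params$atp_reservoir_phi > 0)
    mu_atp_reservoir(params$atp_reservoir_phi, params) else 0
  .xlx(phi) / params$protein$N1 + .xlx(S) / params$N2 + .xlx(lam * phi) +
    params$chi * lam * phi * S - lam * phi * mub
}

#' Binding free energy with both Tyr-Arg and ATP-Arg bonds
#'
#' Stirling form of `-(v/V) log Z` for the coupled one-to-one (Tyr-Arg)
#' and one-to-multiple (ATP-Arg, valence L) association.  Tyr and ATP
#' sites carry their own occupancy entropies; the shared free-Arg
#' entropy uses the total bound fraction
#' `t = p m1/m2 + q L lam N1/m2`, which couples p and q (the
#' competition between protein-protein and ATP-protein binding).  Both
#' attachment terms carry the same Euler `-1` as in
#' [f_binding_pure()].
#'
#' @inheritParams f_reference_atp
#' @param p fraction of Tyr in Tyr-Arg bonds.
#' @param q fraction of ATP binding sites occupied by Arg.
#' @return Dimensionless free energy density.
#' @export
f_binding_atp <- function(phi, lam, p, q, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(phi <= 0 | phi >= 1)) stop("phi must lie in (0, 1)")
  pr <- params$protein; L <- params$L
  t <- p * pr$m1 / pr$m2 + q * L * lam * pr$N1 / pr$m2
  if (any(p < 0 | p > 1 | q < 0 | q > 1 | t > 1))
    stop("(p, q, lam) outside the feasible Arg budget")
  att <- log(pr$m2 * phi / pr$N1)
  (pr$m1 * phi / pr$N1) * (.xlx(p) + .xlx(1 - p)) +
    L * lam * phi * (.xlx(q) + .xlx(1 - q)) +
    (pr$m2 * phi / pr$N1) * .xlx(1 - t) -
    (p * pr$m1 * phi / pr$N1) * (att - params$beta_eps1 - 1) -
    (q * L * lam * phi) * (att - params$beta_eps2 - 1)
}

# Solve t = rp * p(t) + a * q(t) with p = K1 u/(1+K1 u),
# q = K2 u/(1+K2 u), u = 1-t.  Safeguarded Newton; unique root since the
# rhs decreases in t.
.solve_t <- function(K1, K2, rp, a, tol = 1e-14) {
  g <- function(t) {
    u <- 1 - t
    rp * K1 * u / (1 + K1 * u) + a * K2 * u / (1 + K2 * u) - t
  }
  if (g(0) <= 0) return(0)
  lo <- 0; hi <- 1; t <- min(0.5, g(0))
  for (i in 1:100) {
    u <- 1 - t
    gv <- rp * K1 * u / (1 + K1 * u) + a * K2 * u / (1 + K2 * u) - t
    if (gv > 0) lo <- t else hi <- t
    dg <- -rp * K1 / (1 + K1 * u)^2 - a * K2 / (1 + K2 * u)^2 - 1
    t_new <- t - gv / dg
    if (!is.finite(t_new) || t_new <= lo || t_new >= hi) t_new <- (lo + hi) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

# Full internal solve at fixed phi and reservoir.  The outer root is in
# x = log(lam/lam_max) so the solvent fraction S = (1-phi)(1 - e^x) stays
# accurate as the box fills with ATP.  Returns p, q, lam plus lamphi and
# S carried at full precision.
.solve_internal_state <- function(phi, params) {
  pr <- params$protein
  if (params$atp_reservoir_phi <= 0 || pr$m2 == 0) {
    p <- solve_p_pure(phi, params)
    t <- if (pr$m2 > 0) p * pr$m1 / pr$m2 else 0
    return(list(p = p, q = 0, lam = 0, lamphi = 0, S = 1 - phi,
                t = t, converged = TRUE))
  }
  mub <- mu_atp_reservoir(params$atp_reservoir_phi, params)
  Ks <- .Kconst(phi, params)
  rp <- pr$m1 / pr$m2
  L <- params$L
  afac <- L * pr$N1 / pr$m2
  chi <- params$chi; N2 <- params$N2
  lam_max <- (1 - phi) / phi
  Rfun <- function(x) {
    lam <- lam_max * exp(x)
    lamphi <- (1 - phi) * exp(x)
    S <- (1 - phi) * (-expm1(x))
    t <- .solve_t(Ks$K1, Ks$K2, rp, afac * lam)
    q <- Ks$K2 * (1 - t) / (1 + Ks$K2 * (1 - t))
    log(lamphi) - log(S) / N2 - 1 / N2 + 1 +
      chi * (1 - phi - 2 * lamphi) + L * log1p(-q) - mub
  }
  x_hi <- -1e-12
  x_lo <- min(log(1e-300) - log(1 - phi), -5)
  converged <- TRUE
  if (Rfun(x_hi) < 0) {
    # ATP floods the box; representable optimum sits at the boundary
    x <- x_hi
    converged <- FALSE
  } else {
    # Rfun -> -Inf as x -> -Inf through log(lamphi)
    while (Rfun(x_lo) > 0 && x_lo > -690) x_lo <- x_lo - 80
    x <- uniroot(Rfun, c(x_lo, x_hi), tol = 1e-15)$root
  }
  lam <- lam_max * exp(x)
  t <- .solve_t(Ks$K1, Ks$K2, rp, afac * lam)
  list(p = Ks$K1 * (1 - t) / (1 + Ks$K1 * (1 - t)),
       q = Ks$K2 * (1 - t) / (1 + Ks$K2 * (1 - t)),
       lam = lam, lamphi = (1 - phi) * exp(x),
       S = (1 - phi) * (-expm1(x)), t = t, converged = converged)
}

#' Self-consistent internal order parameters at fixed composition
#'
#' Minimizes the total free energy over the bond fractions p, q and the
#' ATP loading lambda at fixed protein volume fraction and fixed
#' reservoir chemical potential.  Stationarity reduces to two
#' mass-action relations sharing the free-Arg factor `(1 - t)` plus the
#' equality of the ATP chemical potential inside the solution (with the
#' `L log(1-q)` binding bonus) and in the reservoir; these are solved as
#' nested safeguarded scalar roots.
#'
#' @param phi protein volume fraction in (0, 1).
#' @param params a [model_params()].
#' @return A list of class `internal_state` with elements `p`, `q`,
#'   `lam`, plus the Arg bound fraction `t`, the precise solvent
#'   fraction `S`, ATP volume fraction `lamphi`, and a `converged`
#'   flag (FALSE only in the extreme ATP-flooded regime where the
#'   optimum is at the representable boundary).
#' @export
solve_internal <- function(phi, params) {
  stopifnot(inherits(params, "model_params"))
  if (length(phi) != 1 || phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)")
  st <- .solve_internal_state(phi, params)
  structure(st, class = "internal_state")
}

#' Total mean-field free energy at the internal optimum
#'
#' `f_ref + f_binding` evaluated at the [solve_internal()] optimum.  By
#' the envelope theorem its total derivative in phi equals the partial
#' derivative at fixed (p, q, lambda), which is what the phase-diagram
#' solver uses.
#'
#' @inheritParams solve_internal
#' @return A list with `f` (free energy density) and `state` (the
#'   `internal_state`).
#' @export
f_total <- function(phi, params) {
  stopifnot(inherits(params, "model_params"))
  if (length(phi) != 1 || phi <= 0 || phi >= 1) stop("phi must lie in (0, 1)")
  st <- .solve_internal_state(phi, params)
  list(f = .f_total_at(phi, st, params), state = st)
}

# free energy at explicit internal state (uses the high-precision
# lamphi/S carried by the state)
.f_total_at <- function(phi, st, params) {
  pr <- params$protein; L <- params$L
  lamphi <- st$lamphi; S <- st$S
  mub <- if (params$atp_reservoir_phi > 0)
    mu_atp_reservoir(params$atp_reservoir_phi, params) else 0
  fref <- .xlx(phi) / pr$N1 + .xlx(S) / params$N2 + .xlx(lamphi) +
    params$chi * lamphi * S - lamphi * mub
  p <- st$p; q <- st$q
  t <- st$t
  att <- log(pr$m2 * phi / pr$N1)
  fb <- (pr$m1 * phi / pr$N1) * (.xlx(p) + .xlx(1 - p)) +
    L * lamphi * (.xlx(q) + .xlx(1 - q)) +
    (pr$m2 * phi / pr$N1) * .xlx(1 - t) -
    (p * pr$m1 * phi / pr$N1) * (att - params$beta_eps1 - 1) -
    (q * L * lamphi) * (att - params$beta_eps2 - 1)
  fref + fb
}

# binding part only, at explicit state (for the envelope derivative:
# d f_bind / d phi = f_bind/phi - (p m1/N1 + q L lam))
.f_bind_at <- function(phi, st, params) {
  pr <- params$protein; L <- params$L
  p <- st$p; q <- st$q; lamphi <- st$lamphi
  t <- st$t
  att <- log(pr$m2 * phi / pr$N1)
  (pr$m1 * phi / pr$N1) * (.xlx(p) + .xlx(1 - p)) +
    L * lamphi * (.xlx(q) + .xlx(1 - q)) +
    (pr$m2 * phi / pr$N1) * .xlx(1 - t) -
    (p * pr$m1 * phi / pr$N1) * (att - params$beta_eps1 - 1) -
    (q * L * lamphi) * (att - params$beta_eps2 - 1)
}
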