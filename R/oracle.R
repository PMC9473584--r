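# Exact finite-size evaluation of the association partition function.
# Serves as the independent arbiter for the Stirling free energies.

#' Define a finite system composition
#'
#' @param n_p number of protein chains.
#' @param n_s number of solvent chains.
#' @param n_atp number of ATP molecules.
#' @return A list of class `system_composition`.
#' @export
system_composition <- function(n_p, n_s, n_atp = 0) {
  stopifnot(n_p >= 0, n_s >= 0, n_atp >= 0)
  structure(list(n_p = as.numeric(n_p), n_s = as.numeric(n_s),
                 n_atp = as.numeric(n_atp)),
            class = "system_composition")
}

#' Exact association free energy by direct enumeration
#'
#' Sums the partition function
#' `Z = sum_{k,b} C(n_p m1, k) C(n_atp L, b) C(n_p m2, k+b) (k+b)!
#'  (v/V)^{k+b} exp(-k beta_eps1 - b beta_eps2)`
#' over all bond numbers (k Tyr-Arg bonds, b ATP-Arg bonds) with no
#' Stirling approximation, in log space, and returns the binding free
#' energy density `-(v/V) log Z`.  This is the small-system oracle the
#' mean-field [f_binding_pure()] / [f_binding_atp()] must converge to
#' as the composition is scaled up at fixed volume fractions.
#'
#' @param comp a [system_composition()].
#' @param params a [model_params()].
#' @param max_terms guard on the size of the (k, b) grid.
#' @return Dimensionless free energy density `-(v/V) log Z`.
#' @examples
#' pars <- model_params(protein_spec(10, 1, 1))
#' comp <- system_composition(1, 10, 0)
#' exact_association_oracle(comp, pars)
#' @export
exact_association_oracle <- function(comp, params, max_terms = 4e6) {
  stopifnot(inherits(comp, "system_composition"),
            inherits(params, "model_params"))
  pr <- params$protein
  M1 <- comp$n_p * pr$m1
  M2 <- comp$n_p * pr$m2
  A  <- comp$n_atp * params$L
  V  <- comp$n_p * pr$N1 + comp$n_s * params$N2 + comp$n_atp  # units of v
  if (V <= 0) stop("empty system")
  vV <- 1 / V
  kmax <- min(M1, M2)
  bmax_all <- min(A, M2)
  if ((kmax + 1) * (bmax_all + 1) > max_terms)
    stop("composition too large for exact enumeration")
  logvV <- log(vV)
  lse <- -Inf
  for (k in 0:kmax) {
    b <- 0:min(A, M2 - k)
    lt <- lchoose(M1, k) + lchoose(A, b) + lchoose(M2, k + b) +
      lfactorial(k + b) + (k + b) * logvV -
      k * params$beta_eps1 - b * params$beta_eps2
    m <- max(lt, lse)
    lse <- m + log(exp(lse - m) + sum(exp(lt - m)))
  }
  -vV * lse
}

#' Mean-field binding free energy matched to a finite composition
#'
#' Convenience helper for oracle comparisons: converts a
#' [system_composition()] to (phi, lambda), minimizes the Stirling
#' binding free energy over the bond fractions at that fixed
#' composition (no reservoir), and returns the result on the same
#' density scale as [exact_association_oracle()].
#'
#' @inheritParams exact_association_oracle
#' @return A list with `f` (Stirling binding free energy density),
#'   `phi`, `lam`, and the minimizing `p`, `q`.
#' @export
stirling_binding_matched <- function(comp, params) {
  stopifnot(inherits(comp, "system_composition"),
            inherits(params, "model_params"))
  pr <- params$protein
  V <- comp$n_p * pr$N1 + comp$n_s * params$N2 + comp$n_atp
  phi <- comp$n_p * pr$N1 / V
  lam <- if (comp$n_p > 0) comp$n_atp / (comp$n_p * pr$N1) else 0
  Ks <- .Kconst(phi, params)
  rp <- pr$m1 / pr$m2
  a <- params$L * lam * pr$N1 / pr$m2
  t <- .solve_t(Ks$K1, Ks$K2, rp, a)
  p <- Ks$K1 * (1 - t) / (1 + Ks$K1 * (1 - t))
  q <- Ks$K2 * (1 - t) / (1 + Ks$K2 * (1 - t))
  f <- if (comp$n_atp > 0) f_binding_atp(phi, lam, p, q, params)
       else f_binding_pure(phi, p, params)
  list(f = f, phi = phi, lam = lam, p = p, q = q)
}
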