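# Shared fixtures for the suite.

fus_pure <- function(...) {
  p <- fus_profile("fus2022", ...)
  p$atp_reservoir_phi <- 0
  p
}

# small protein for enumeration-oracle comparisons
tiny_params <- function(n_atp = FALSE) {
  if (n_atp)
    model_params(protein_spec(10, 2, 2), N2 = 5, beta_eps1 = -2,
                 L = 2, beta_eps2 = -3)
  else
    model_params(protein_spec(10, 2, 2), N2 = 5, beta_eps1 = -2)
}

# total free energy at explicit internal state, via exported pieces
f_at_state <- function(phi, lam, p, q, params) {
  f_reference_atp(phi, lam, params) + f_binding_atp(phi, lam, p, q, params)
}

# reduced-scale CG slab used across the CG tests
small_slab <- function(n_atp = 0, seed = 1, ...) {
  build_slab_system(list(n_chains = 10, chain_length = 34, n_atp = n_atp,
                         box = c(30, 30, 90), slab_fraction = 0.3, ...),
                    seed = seed)
}
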