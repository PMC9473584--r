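# Phase-diagram scans and derived figure-style summaries.

.coex_row <- function(cx) {
  data.frame(coexists = cx$converged, clipped = isTRUE(cx$clipped),
             phi_dilute = cx$phi_dilute, phi_dense = cx$phi_dense,
             rho_dilute = cx$rho_dilute, rho_dense = cx$rho_dense,
             p_dilute = cx$p_dilute, p_dense = cx$p_dense,
             q_dense = cx$q_dense, g_dense = cx$g_dense,
             residual_mu = cx$residual_mu, residual_Pi = cx$residual_Pi)
}

#' Binodal scan along the Tyr-Arg binding energy
#'
#' Solves the ATP-free tie-line for each binding energy and returns one
#' row per scan point with both binodal branches and the bond fraction
#' in each phase.
#'
#' @param eps1_values Tyr-Arg binding energies in kT.
#' @param params a [model_params()].
#' @return A data.frame with columns `beta_eps1`, `coexists`,
#'   `phi_dilute`, `phi_dense`, `rho_dilute`, `rho_dense`,
#'   `p_dilute`, `p_dense`, residuals.
#' @export
scan_binding_energy <- function(eps1_values, params) {
  stopifnot(inherits(params, "model_params"))
  rows <- lapply(eps1_values, function(e) {
    params$beta_eps1 <- e
    cx <- tryCatch(solve_coexistence(params),
                   error = function(err) NULL)
    if (is.null(cx)) cx <- structure(list(converged = FALSE), class = "x")
    if (!isTRUE(cx$converged))
      cx <- solve_coexistence(params, n_grid = 10)  # canonical empty result
    cbind(data.frame(beta_eps1 = e), .coex_row(cx))
  })
  do.call(rbind, rows)
}

#' Phase-diagram scan along the reservoir ATP concentration
#'
#' For each reservoir concentration, converts to the ATP volume
#' fraction, solves the tie-line, and reports the dilute/dense branches
#' together with the condensate observables: dense-phase Tyr-Arg bond
#' fraction `p_dense` and bound Arg per ATP `g_dense = L * q_dense`.
#'
#' @param c_values reservoir ATP concentrations in mol/L.
#' @param params a [model_params()].
#' @return A data.frame with one row per concentration.
#' @export
scan_atp <- function(c_values, params) {
  stopifnot(inherits(params, "model_params"))
  rows <- lapply(c_values, function(cc) {
    params$atp_reservoir_phi <-
      molar_to_phi(cc, 1, params$residue_size_nm)
    cx <- tryCatch(solve_coexistence(params), error = function(err) NULL)
    if (is.null(cx) || !isTRUE(cx$converged))
      cx <- structure(list(converged = FALSE, clipped = FALSE,
                           phi_dilute = NA_real_, phi_dense = NA_real_,
                           rho_dilute = NA_real_, rho_dense = NA_real_,
                           p_dilute = NA_real_, p_dense = NA_real_,
                           q_dense = NA_real_, g_dense = NA_real_,
                           residual_mu = NA_real_, residual_Pi = NA_real_),
                      class = "coexistence_result")
    cbind(data.frame(c_molar = cc,
                     phi_bar = molar_to_phi(cc, 1, params$residue_size_nm)),
          .coex_row(cx))
  })
  do.call(rbind, rows)
}

#' Closed-loop phase-diagram metrics for asymmetric sticker counts
#'
#' Runs [scan_atp()] for two protein variants (typically m1 > m2 and
#' m1 < m2, where the pure solutions do not phase separate and ATP
#' opens a closed binodal loop) and summarizes each loop: its area and
#' the ATP-Arg engagement `g_dense` along the scan.  The loop area is
#' the integral of `log10(rho_dense) - log10(rho_dilute)` over
#' `log10(c)` (trapezoidal), i.e. the area enclosed by the binodal in
#' doubly logarithmic coordinates; a linear-coordinate variant is also
#' reported.
#'
#' @param params_a,params_b [model_params()] for the two variants.
#' @param c_values reservoir ATP concentrations in mol/L.
#' @return A list with the two scan tables, loop areas, mean `g_dense`
#'   over the common coexistence window, and flags for coexistence in
#'   the ATP-free limit.
#' @export
asymmetric_loop_metrics <- function(params_a, params_b, c_values) {
  scan_a <- scan_atp(c_values, params_a)
  scan_b <- scan_atp(c_values, params_b)
  area <- function(sc, transform = log10) {
    i <- which(sc$coexists)
    if (length(i) < 2) return(0)
    x <- log10(sc$c_molar[i])
    w <- transform(sc$rho_dense[i]) - transform(sc$rho_dilute[i])
    sum(diff(x) * (head(w, -1) + tail(w, -1)) / 2)
  }
  both <- which(scan_a$coexists & scan_b$coexists)
  list(scan_a = scan_a, scan_b = scan_b,
       area_log_a = area(scan_a), area_log_b = area(scan_b),
       area_lin_a = area(scan_a, identity), area_lin_b = area(scan_b, identity),
       g_dense_a = scan_a$g_dense, g_dense_b = scan_b$g_dense,
       mean_g_common_a = if (length(both)) mean(scan_a$g_dense[both]) else NA_real_,
       mean_g_common_b = if (length(both)) mean(scan_b$g_dense[both]) else NA_real_,
       coexist_no_atp_a = .has_coexistence(.zero_atp(params_a)),
       coexist_no_atp_b = .has_coexistence(.zero_atp(params_b)))
}

.zero_atp <- function(params) { params$atp_reservoir_phi <- 0; params }

#' Free-energy curve across composition
#'
#' Evaluates the reference, binding and total free-energy densities and
#' the internal order parameters on a composition grid; the standard
#' export behind the CSV interface.
#'
#' @param params a [model_params()].
#' @param phi composition grid in (0, 1).
#' @return A data.frame with columns `phi, f_ref, f_bind, f_total, p,
#'   q, lam`.
#' @export
free_energy_curve <- function(params,
                              phi = .phi_grid(200, 1e-6, 0.9)) {
  stopifnot(inherits(params, "model_params"))
  rows <- lapply(phi, function(x) {
    st <- .solve_internal_state(x, params)
    fb <- .f_bind_at(x, st, params)
    ft <- .f_total_at(x, st, params)
    data.frame(phi = x, f_ref = ft - fb, f_bind = fb, f_total = ft,
               p = st$p, q = st$q, lam = st$lam)
  })
  do.call(rbind, rows)
}
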