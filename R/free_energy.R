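#' Free-energy parameters for the RNA-protein mixture
#'
#' Bundles the coefficients of the bulk free-energy density
#' \deqn{f(\phi_P, \phi_R) = \rho_P (\phi_P-\alpha)^2 (\phi_P-\beta)^2
#'   - \chi \phi_P \phi_R + c\, \phi_P^2 \phi_R^2 + \rho_R \phi_R^2,}
#' together with the square-gradient (surface energy) coefficient
#' \eqn{\kappa} used by the dynamics, where the full free-energy functional
#' adds \eqn{(\kappa/2)|\nabla \phi_P|^2}.
#'
#' The double well places the pure-protein binodals at \eqn{\alpha}
#' (dilute) and \eqn{\beta} (dense). \eqn{\chi} is the heterotypic
#' RNA-protein attraction, \eqn{c} the quartic RNA-protein repulsion that
#' produces re-entrant phase behaviour at high RNA, and \eqn{\rho_R} the
#' RNA self-repulsion. All quantities are in simulation units (energy and
#' concentration scales of order one).
#'
#' @param rho_P double-well strength (> 0).
#' @param alpha dilute binodal concentration, \eqn{0 \le \alpha < \beta}.
#' @param beta dense binodal concentration.
#' @param chi RNA-protein attraction (>= 0).
#' @param c_rep quartic RNA-protein repulsion (>= 0).
#' @param rho_R RNA self-repulsion (>= 0).
#' @param kappa square-gradient coefficient (>= 0); only enters the
#'   dynamics and the interfacial profile, never the bulk equilibrium.
#' @return An object of class `fe_params`.
#' @seealso [calibrate_defaults()] for the package's calibrated defaults.
#' @export
#' @examples
#' p <- fe_params()
#' bulk_energy(0.4, 0, p)
fe_params <- function(rho_P = 1, alpha = 0.1, beta = 0.7,
                      chi = 0.8, c_rep = 3.0, rho_R = 1.0, kappa = 0.04) {
  vals <- c(rho_P = rho_P, alpha = alpha, beta = beta, chi = chi,
            c_rep = c_rep, rho_R = rho_R, kappa = kappa)
  if (!all(is.finite(vals)))
    stop("all free-energy parameters must be finite")
  if (rho_P <= 0) stop("rho_P must be > 0")
  if (chi < 0 || c_rep < 0 || rho_R < 0 || kappa < 0)
    stop("chi, c_rep, rho_R and kappa must be >= 0")
  if (!(alpha >= 0 && alpha < beta))
    stop("need 0 <= alpha < beta")
  structure(as.list(vals), class = "fe_params")
}

#' @export
print.fe_params <- function(x, ...) {
  cat("Free-energy parameters (bulk + gradient):\n")
  cat(sprintf("  double well: rho_P = %g, alpha = %g, beta = %g\n",
              x$rho_P, x$alpha, x$beta))
  cat(sprintf("  coupling:    chi = %g, c_rep = %g, rho_R = %g\n",
              x$chi, x$c_rep, x$rho_R))
  cat(sprintf("  gradient:    kappa = %g\n", x$kappa))
  invisible(x)
}

.check_fields <- function(phi_P, phi_R) {
  if (!all(is.finite(phi_P)) || !all(is.finite(phi_R)))
    stop("non-finite concentration encountered (corrupted state)")
}

#' Bulk free-energy density
#'
#' Evaluates the bulk (local) part of the free energy at given protein and
#' RNA concentrations. The gradient term is excluded; it is handled by the
#' dynamics. Negative concentrations are permitted (the polynomial is
#' defined there); they can occur transiently during integration.
#'
#' @param phi_P,phi_R protein / RNA concentrations (vectors recycle).
#' @param p an [fe_params()] object.
#' @return Energy density, same shape as the inputs.
#' @export
bulk_energy <- function(phi_P, phi_R, p) {
  .check_fields(phi_P, phi_R)
  p$rho_P * (phi_P - p$alpha)^2 * (phi_P - p$beta)^2 -
    p$chi * phi_P * phi_R +
    p$c_rep * phi_P^2 * phi_R^2 +
    p$rho_R * phi_R^2
}

#' Chemical potentials of protein and RNA
#'
#' `mu_P()` returns \eqn{\partial f/\partial \phi_P}; when `lap_phi_P`
#' (the discrete Laplacian of the protein field) is supplied it returns the
#' full functional derivative
#' \eqn{\delta F/\delta \phi_P = \partial f/\partial \phi_P - \kappa
#' \nabla^2 \phi_P}, which is what the conserved Model B dynamics
#' transports. The equilibrium solver uses the bulk form only.
#' `mu_R()` is \eqn{\partial f/\partial \phi_R}.
#'
#' @inheritParams bulk_energy
#' @param lap_phi_P optional Laplacian of `phi_P` for the gradient
#'   contribution (`NULL` = bulk part only).
#' @return Chemical potential, same shape as the inputs.
#' @export
mu_P <- function(phi_P, phi_R, p, lap_phi_P = NULL) {
  .check_fields(phi_P, phi_R)
  dP <- phi_P - p$alpha
  dB <- phi_P - p$beta
  out <- 2 * p$rho_P * (dP * dB^2 + dP^2 * dB) -
    p$chi * phi_R + 2 * p$c_rep * phi_P * phi_R^2
  if (!is.null(lap_phi_P)) out <- out - p$kappa * lap_phi_P
  out
}

#' @rdname mu_P
#' @export
mu_R <- function(phi_P, phi_R, p) {
  .check_fields(phi_P, phi_R)
  -p$chi * phi_P + 2 * p$c_rep * phi_P^2 * phi_R + 2 * p$rho_R * phi_R
}

# second partials of the bulk density; internal
.fe_hessian <- function(phi_P, phi_R, p) {
  dP <- phi_P - p$alpha
  dB <- phi_P - p$beta
  list(
    f_pp = 2 * p$rho_P * (dB^2 + 4 * dP * dB + dP^2) + 2 * p$c_rep * phi_R^2,
    f_rr = 2 * p$c_rep * phi_P^2 + 2 * p$rho_R,
    f_pr = -p$chi + 4 * p$c_rep * phi_P * phi_R
  )
}

#' Local stability determinant of the bulk free energy
#'
#' Determinant of the Hessian of the bulk free-energy density with respect
#' to \eqn{(\phi_P, \phi_R)}. Compositions with a negative determinant are
#' locally unstable; the sign-change bands mark condensate interfaces
#' (spinodal composition bands crossed by the interfacial profile).
#'
#' @inheritParams bulk_energy
#' @return Signed determinant, same shape as the inputs.
#' @export
stability_det <- function(phi_P, phi_R, p) {
  .check_fields(phi_P, phi_R)
  h <- .fe_hessian(phi_P, phi_R, p)
  h$f_pp * h$f_rr - h$f_pr^2
}

#' Dilute-limit protein diffusivity
#'
#' Linearizing the conserved protein dynamics about the dilute state
#' \eqn{(\phi_P, \phi_R) = (0, 0)} gives an effective diffusion
#' coefficient \eqn{D_P = M_p\, \partial^2 f/\partial \phi_P^2|_{0,0}
#' = 2 M_p \rho_P(\alpha^2 + 4\alpha\beta + \beta^2)}, used to
#' non-dimensionalize condensate drift velocities.
#'
#' @param p an [fe_params()] object.
#' @param M_p protein mobility.
#' @return Effective diffusivity \eqn{D_P} (1.56 for the default well with
#'   `M_p = 1`).
#' @export
protein_diffusivity <- function(p, M_p = 1) {
  M_p * 2 * p$rho_P * (p$alpha^2 + 4 * p$alpha * p$beta + p$beta^2)
}
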