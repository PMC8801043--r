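# Constitutive closures of the morphoelastic model, evaluated nodewise.
#
# Species z in {c, N, M, rho} obey  dz/dt + (z v)' = -J_z' + R_z ;
# the velocity obeys  rho_t (dv/dt + 2 v v') = sigma' + f ;
# the effective strain obeys  deps/dt + v eps' + (eps - 1) v' = -G.
# The four functions below define J_z, R_z, (sigma, f) and G. They are the
# single R-level statement of the closure family; the compiled solver
# assembles the same terms in linearised (Picard) form.

#' Reaction terms of the four species
#'
#' Chemical response rates evaluated nodewise:
#' \describe{
#'   \item{c}{secretion `k_c c/(a_c_II + c) (N + eta_I M)` minus proteolytic
#'     decay `delta_c (N + eta_I M) rho c`;}
#'   \item{N}{logistic proliferation with chemical enhancement
#'     `r_F (1 + r_F_max c/(a_c_I + c)) (1 - kappa_F (N + M)) N`, minus
#'     differentiation `k_F c N` and apoptosis `delta_N N`;}
#'   \item{M}{enhanced proliferation
#'     `r_F (1 + r_F_max) c/(a_c_I + c) (1 - kappa_F (N + M)) M`, plus
#'     differentiation influx `k_F c N`, minus apoptosis `delta_M M`;}
#'   \item{rho}{production
#'     `k_rho (1 + k_rho_max c/(a_c_IV + c)) (N + eta_II M)` minus
#'     density-dependent degradation `delta_rho (N + eta_I M) rho`.}
#' }
#' All four vanish at the homeostatic equilibrium.
#'
#' @param state A `scar_state`.
#' @param params A `scar_params`.
#' @return List of numeric nodal vectors `c`, `N`, `M`, `rho`.
#' @export
reaction_terms <- function(state, params) {
  validate_state(state)
  p <- params
  cc <- state[, "c"]; N <- state[, "N"]; M <- state[, "M"]
  rho <- state[, "rho"]
  cells_I <- N + p$eta_I * M
  crowd <- 1 - p$kappa_F * (N + M)
  enh <- cc / (p$a_c_I + cc)
  list(
    c   = p$k_c * cc / (p$a_c_II + cc) * cells_I - p$delta_c * cells_I * rho * cc,
    N   = p$r_F * (1 + p$r_F_max * enh) * crowd * N - p$k_F * cc * N -
          p$delta_N * N,
    M   = p$r_F * (1 + p$r_F_max) * enh * crowd * M + p$k_F * cc * N -
          p$delta_M * M,
    rho = p$k_rho * (1 + p$k_rho_max * cc / (p$a_c_IV + cc)) *
          (N + p$eta_II * M) - p$delta_rho * cells_I * rho
  )
}

#' Non-convective fluxes of the four species
#'
#' Fickian diffusion for the signalling molecule
#' (`J_c = -D_c c'`), density-dependent random walk plus chemotaxis for the
#' cells (`J_N = -D_F (N + M) N' + chi_F N c'`, likewise for `M`), and no
#' flux for collagen (`J_rho = 0`: collagen does not migrate).
#'
#' @inheritParams reaction_terms
#' @param mesh A `scar_mesh` (needed for spatial gradients).
#' @return List of numeric nodal vectors `c`, `N`, `M`, `rho`.
#' @export
flux_terms <- function(state, params, mesh) {
  validate_state(state)
  p <- params
  dc <- nodal_gradient(state[, "c"], mesh$x)
  dN <- nodal_gradient(state[, "N"], mesh$x)
  dM <- nodal_gradient(state[, "M"], mesh$x)
  Ftot <- state[, "N"] + state[, "M"]
  list(
    c   = -p$D_c * dc,
    N   = -p$D_F * Ftot * dN + p$chi_F * state[, "N"] * dc,
    M   = -p$D_F * Ftot * dM + p$chi_F * state[, "M"] * dc,
    rho = rep(0, nrow(state))
  )
}

#' Stress and cell-traction body force
#'
#' The dermal stress combines a viscous part and an elastic part whose
#' stiffness grows with collagen density:
#' `sigma = mu v' + E_mod sqrt(rho) eps`. The body force is the spatial
#' derivative of the myofibroblast traction potential
#' `psi = xi M rho / (R_sat^2 + rho^2)`, i.e. `f = psi'`. Both vanish at the
#' homeostatic equilibrium (no strain, no myofibroblasts).
#'
#' @inheritParams flux_terms
#' @return List with numeric nodal vectors `sigma` and `f`.
#' @export
stress_body_force <- function(state, params, mesh) {
  validate_state(state)
  p <- params
  dv <- nodal_gradient(state[, "v"], mesh$x)
  sigma <- p$mu * dv + p$E_mod * sqrt(state[, "rho"]) * state[, "eps"]
  psi <- p$xi * state[, "M"] * state[, "rho"] /
    (p$R_sat^2 + state[, "rho"]^2)
  list(sigma = sigma, f = nodal_gradient(psi, mesh$x))
}

#' Plastic growth term of the effective strain
#'
#' `G = zeta * c/(a_c_III + c) * M * eps`: permanent-strain conversion
#' requires active myofibroblasts, signalling, and elastic strain; it relaxes
#' the effective strain so contraction becomes (partly) permanent.
#'
#' @inheritParams reaction_terms
#' @return Numeric nodal vector `G`.
#' @export
growth_term <- function(state, params) {
  validate_state(state)
  p <- params
  p$zeta * state[, "c"] / (p$a_c_III + state[, "c"]) * state[, "M"] *
    state[, "eps"]
}

# central differences on a (possibly nonuniform) mesh; one-sided at the ends
nodal_gradient <- function(u, x) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (u[2] - u[1]) / (x[2] - x[1])
  g[n] <- (u[n] - u[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    g[2:(n - 1)] <- (u[3:n] - u[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  }
  g
}
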