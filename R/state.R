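# Nodal state container and the initial wound profile.

.state_cols <- c("c", "N", "M", "rho", "v", "eps")

#' Nodal state of the morphoelastic model
#'
#' Holds the six unknowns at every mesh node: signalling concentration `c`
#' (g/cm^3), fibroblasts `N` and myofibroblasts `M` (cells/cm^3), collagen
#' `rho` (g/cm^3), displacement velocity `v` (cm/day) and effective strain
#' `eps` (dimensionless).
#'
#' @param c,N,M,rho,v,eps Numeric nodal vectors of equal length.
#' @param time Simulation time in days.
#' @return A `scar_state`: a numeric matrix with one column per field and a
#'   `time` attribute.
#' @export
scar_state <- function(c, N, M, rho, v, eps, time = 0) {
  m <- cbind(c = c, N = N, M = M, rho = rho, v = v, eps = eps)
  storage.mode(m) <- "double"
  attr(m, "time") <- as.numeric(time)
  class(m) <- c("scar_state", "matrix", "array")
  validate_state(m)
}

validate_state <- function(state) {
  if (any(!is.finite(state))) stop("non-finite state value", call. = FALSE)
  if (any(state[, c("c", "N", "M", "rho")] < 0)) {
    stop("species concentrations must be nonnegative", call. = FALSE)
  }
  if (any(state[, "eps"] >= 1)) {
    stop("effective strain must stay below 1", call. = FALSE)
  }
  invisible(state)
}

#' @export
print.scar_state <- function(x, ...) {
  cat(sprintf("scar_state: %d nodes at t = %.4g days\n", nrow(x),
              attr(x, "time")))
  rng <- apply(x, 2, range)
  for (nm in colnames(x)) {
    cat(sprintf("  %-4s in [%.4g, %.4g]\n", nm, rng[1, nm], rng[2, nm]))
  }
  invisible(x)
}

#' Uniform finite-element mesh
#'
#' Uniform 1D mesh on the symmetric half domain `[0, domain_length]`; the
#' symmetry plane of the wound sits at x = 0.
#'
#' @param params A `scar_params` object (supplies the domain length), or a
#'   single numeric domain length.
#' @param n_nodes Number of nodes (default 202, i.e. the reference spatial
#'   resolution of the model on a 10 cm domain).
#' @return Object of class `scar_mesh` with elements `x` (node coordinates)
#'   and `h` (element lengths).
#' @export
scar_mesh <- function(params, n_nodes = 202L) {
  len <- if (inherits(params, "scar_params")) params$domain_length
         else as.numeric(params)
  if (!is.finite(len) || len <= 0) stop("domain length must be positive")
  if (n_nodes < 3) stop("mesh needs at least 3 nodes")
  x <- seq(0, len, length.out = n_nodes)
  structure(list(x = x, h = diff(x)), class = "scar_mesh")
}

#' @export
print.scar_mesh <- function(x, ...) {
  cat(sprintf("scar_mesh: %d nodes on [0, %.4g] cm (h = %.4g cm)\n",
              length(x$x), max(x$x), x$h[1]))
  invisible(x)
}

#' Initial condition with (or without) a wound
#'
#' The wound occupies `[0, L)`; nodal fields transition smoothly between
#' wounded and healthy values through the sigmoidal profile
#' `w(x) = 1 / (1 + exp(steepness * (x - L)))`. Inside the wound the
#' signalling concentration is `c_w`, fibroblasts and collagen are reduced to
#' the configured fractions of their equilibrium values, and no
#' myofibroblasts are present (they arise through differentiation).
#'
#' @param params A `scar_params` object.
#' @param mesh A `scar_mesh`.
#' @param wounded If `FALSE`, return the homeostatic equilibrium instead.
#' @return A `scar_state`.
#' @export
initial_state <- function(params, mesh = scar_mesh(params), wounded = TRUE) {
  if (!wounded) return(equilibrium_state(params, mesh))
  w <- wound_profile(mesh$x, params$L, params$steepness)
  scar_state(
    c   = params$c_w * w,
    N   = params$N_bar * (params$wound_N_frac * w + (1 - w)),
    M   = rep(0, length(mesh$x)),
    rho = params$rho_bar * (params$wound_rho_frac * w + (1 - w)),
    v   = rep(0, length(mesh$x)),
    eps = rep(0, length(mesh$x)),
    time = 0)
}

wound_profile <- function(x, L, steepness) {
  1 / (1 + exp(steepness * (x - L)))
}
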