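# R interface to the compiled FEM solver.

#' Solver control settings
#'
#' @param dt Time step in days (default 1; `1/dt` must be a whole number so
#'   the relative surface area can be recorded once per day).
#' @param days Total simulated time in days (default 365).
#' @param picard_tol Relative-update tolerance of the inner Picard loop
#'   (combined over all six unknowns, each scaled by its field magnitude).
#' @param picard_max Maximum Picard iterations per time step.
#' @param boundary `"far-field"` (default) pins the dermal far end at its
#'   healthy equilibrium; `"closed"` imposes no-flux conditions everywhere
#'   (used for spatially homogeneous reductions).
#' @param snapshot_every Store full state snapshots every this many days
#'   (0 = none).
#' @return Object of class `scar_control`.
#' @export
scar_control <- function(dt = 1, days = 365, picard_tol = 1e-4,
                         picard_max = 50L,
                         boundary = c("far-field", "closed"),
                         snapshot_every = 0L) {
  boundary <- match.arg(boundary)
  if (dt <= 0) stop("dt must be positive")
  spd <- 1 / dt
  if (abs(spd - round(spd)) > 1e-9) {
    stop("1/dt must be a whole number of steps per day")
  }
  if (days < 1) stop("days must be at least 1")
  structure(list(dt = dt, days = as.integer(days), picard_tol = picard_tol,
                 picard_max = as.integer(picard_max), boundary = boundary,
                 snapshot_every = as.integer(snapshot_every),
                 steps_per_day = as.integer(round(spd))),
            class = "scar_control")
}

#' Assemble one Picard linear system
#'
#' Builds the (scaled) block-tridiagonal linear system whose solution is the
#' next Picard iterate of the monolithic backward-Euler step: nonlinear
#' coefficients are frozen at the supplied iterate, the time derivative uses
#' the previous time level.
#'
#' @param state_prev State at the previous time level (`scar_state`).
#' @param iterate Current Picard iterate (defaults to `state_prev`).
#' @param mesh A `scar_mesh`.
#' @param params A `scar_params`.
#' @param dt Time step (days).
#' @param control A `scar_control` (supplies the boundary mode).
#' @return List with 6x6 block arrays `D` (diagonal), `Up`, `Lo`
#'   (off-diagonal), right-hand side `rhs` (nodes x 6) and the per-field
#'   `scale` used to nondimensionalise the unknowns.
#' @export
assemble_step <- function(state_prev, iterate = state_prev, mesh, params,
                          dt = 1, control = scar_control(dt = dt)) {
  validate_state(state_prev)
  validate_state(iterate)
  sys <- cpp_system(unclass(iterate), unclass(state_prev), mesh$x,
                    as_param_vector(params), dt,
                    control$boundary == "closed")
  n <- sys$n
  # compiled blocks are row-major; aperm makes D[, , k] the actual 6x6 block
  list(D = aperm(array(sys$D, c(6, 6, n)), c(2, 1, 3)),
       Up = aperm(array(sys$Up, c(6, 6, n - 1)), c(2, 1, 3)),
       Lo = aperm(array(sys$Lo, c(6, 6, n - 1)), c(2, 1, 3)),
       rhs = matrix(sys$rhs, ncol = 6, byrow = TRUE),
       scale = sys$scale, n = n)
}

# residual of a block-tridiagonal system at a given (unscaled) state
system_residual <- function(sys, state) {
  n <- sys$n
  u <- t(unclass(state)) / sys$scale      # 6 x n, scaled unknowns
  r <- matrix(0, 6, n)
  for (k in seq_len(n)) {
    r[, k] <- sys$D[, , k] %*% u[, k]
    if (k > 1) r[, k] <- r[, k] + sys$Lo[, , k - 1] %*% u[, k - 1]
    if (k < n) r[, k] <- r[, k] + sys$Up[, , k] %*% u[, k + 1]
  }
  r - t(sys$rhs)
}

#' Advance the state by one backward-Euler step
#'
#' Runs the inner Picard loop to convergence and returns the new state
#' (negative species undershoots clipped to zero).
#'
#' @inheritParams assemble_step
#' @param state State at the current time level.
#' @return A `scar_state` at time `t + dt` with attributes `iters` (Picard
#'   iterations used) and `clipped` (largest clipped mass fraction).
#' @export
time_step <- function(state, mesh, params, control = scar_control()) {
  validate_state(state)
  o <- cpp_step(unclass(state), mesh$x, as_param_vector(params), control$dt,
                control$picard_tol, control$picard_max,
                control$boundary == "closed")
  if (o$status == 1L) {
    stop(sprintf(paste0("Picard iteration did not converge within %d ",
                        "iterations (last relative update %.3g)"),
                 control$picard_max, o$maxrel), call. = FALSE)
  }
  if (o$status == 2L) stop("singular linear system in time step", call. = FALSE)
  if (o$status == 3L) stop("effective strain reached 1", call. = FALSE)
  if (o$status == 4L) {
    stop(sprintf("negativity clip exceeded tolerance (fraction %.3g)",
                 o$clipped), call. = FALSE)
  }
  st <- o$state
  colnames(st) <- .state_cols
  attr(st, "time") <- attr(state, "time") + control$dt
  attr(st, "iters") <- o$iters
  attr(st, "clipped") <- o$clipped
  class(st) <- c("scar_state", "matrix", "array")
  st
}

#' Simulate post-burn scar contraction
#'
#' Runs the full morphoelastic model: six coupled fields discretised with
#' linear finite elements on a moving (updated-Lagrangian) mesh, integrated
#' with backward Euler and inner Picard iterations, and records the relative
#' surface area (RSA) of the wound once per day. The RSA is the current
#' length of the wound interval relative to its initial length; the wound
#' edge is the material point initially at `x = L`.
#'
#' @param params A `scar_params`; must satisfy the stability condition
#'   (see [check_stability()]).
#' @param mesh A `scar_mesh` (default: 202 nodes on the configured domain).
#' @param control A `scar_control`.
#' @param init Initial state (default: the wounded profile of
#'   [initial_state()]).
#' @param wounded Passed to [initial_state()] when `init` is `NULL`.
#' @return Object of class `scar_sim` with elements `rsa` (daily RSA,
#'   length `control$days`), `edge` (daily wound-edge position, cm),
#'   `min_rsa`, `last_rsa`, `state` and `x` (final nodal state and mesh),
#'   `iters` (Picard iterations per step), `max_clipped`, `snapshots`,
#'   `params`, `control`.
#' @examples
#' p <- scar_params()
#' sim <- scar_simulate(p, mesh = scar_mesh(p, 101))
#' print(sim)
#' @export
scar_simulate <- function(params, mesh = scar_mesh(params),
                          control = scar_control(), init = NULL,
                          wounded = TRUE) {
  # lenient form of check_stability(): a switched-off secretion (k_c = 0)
  # is trivially stable, so degenerate test configurations remain runnable
  stable <- params$k_c == 0 ||
    params$k_c < params$delta_c * params$rho_bar * params$a_c_II
  if (!stable) {
    stop("parameter set violates the stability condition k_c < delta_c rho_bar a_c_II",
         call. = FALSE)
  }
  if (is.null(init)) init <- initial_state(params, mesh, wounded = wounded)
  validate_state(init)
  res <- cpp_simulate(unclass(init), mesh$x, as_param_vector(params),
                      control$dt, control$days, control$steps_per_day,
                      control$picard_tol, control$picard_max,
                      control$boundary == "closed", control$snapshot_every)
  if (res$status != 0L) {
    msg <- c("1" = "Picard iteration did not converge",
             "2" = "singular linear system",
             "3" = "effective strain reached 1",
             "4" = "negativity clip exceeded tolerance",
             "5" = "mesh tangling")[as.character(res$status)]
    stop(sprintf("simulation failed at step %d (day %.2f): %s",
                 res$failstep, res$failstep * control$dt, msg), call. = FALSE)
  }
  st <- res$state
  colnames(st) <- .state_cols
  attr(st, "time") <- control$days
  class(st) <- c("scar_state", "matrix", "array")
  structure(list(rsa = res$rsa, edge = res$edge, edge0 = res$edge0,
                 min_rsa = min(res$rsa), last_rsa = res$rsa[length(res$rsa)],
                 state = st, x = res$x, iters = res$iters,
                 max_clipped = res$max_clipped,
                 n_substepped = res$n_substepped, snapshots = res$snapshots,
                 params = params, control = control),
            class = "scar_sim")
}

#' @export
print.scar_sim <- function(x, ...) {
  cat("Morphoelastic contraction simulation\n")
  cat(sprintf("  %d days, dt = %.3g day, %d nodes\n", x$control$days,
              x$control$dt, length(x$x)))
  cat(sprintf("  minimum RSA %.4f at day %d; last RSA %.4f\n",
              x$min_rsa, which.min(x$rsa), x$last_rsa))
  cat(sprintf("  Picard iterations: median %d, max %d\n",
              as.integer(stats::median(x$iters)), max(x$iters)))
  if (x$n_substepped > 0) {
    cat(sprintf("  %d step(s) fell back to refined substeps\n",
                x$n_substepped))
  }
  invisible(x)
}

#' @export
summary.scar_sim <- function(object, ...) {
  cat(sprintf(paste0("RSA course over %d days: min %.4f (day %d), ",
                     "last %.4f, contraction %.1f%%\n"),
              object$control$days, object$min_rsa, which.min(object$rsa),
              object$last_rsa, 100 * (1 - object$min_rsa)))
  invisible(object)
}

#' @export
plot.scar_sim <- function(x, ...) {
  graphics::plot(seq_along(x$rsa), x$rsa, type = "l", xlab = "day",
                 ylab = "relative surface area", ylim = c(0, 1), ...)
  graphics::abline(h = x$min_rsa, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.scar_sim <- function(x, ...) {
  data.frame(day = seq_along(x$rsa), rsa = x$rsa, edge = x$edge)
}

#' Relative surface area from a wound-edge trajectory
#'
#' In one dimension the wound "surface area" is the length of the wound
#' interval, so the RSA course is the edge position relative to its initial
#' value.
#'
#' @param edge Numeric vector of wound-edge positions (cm).
#' @param initial_edge Initial edge position (cm), strictly positive.
#' @return Numeric vector `edge / initial_edge`.
#' @export
compute_rsa <- function(edge, initial_edge) {
  if (!is.finite(initial_edge) || initial_edge <= 0) {
    stop("initial edge position must be strictly positive", call. = FALSE)
  }
  if (any(edge <= 0)) stop("nonpositive edge position", call. = FALSE)
  edge / initial_edge
}

#' Advect a material point through a velocity field
#'
#' Integrates `dx/dt = v(x, t)` with Heun's (explicit trapezoidal) method;
#' used to transport the wound edge through a given velocity field.
#'
#' @param x0 Initial position.
#' @param v Function `v(x, t)` returning the velocity.
#' @param dt Step size (days).
#' @param n_steps Number of steps.
#' @return Numeric vector of positions of length `n_steps + 1` (including
#'   `x0`).
#' @export
advect_edge <- function(x0, v, dt, n_steps) {
  out <- numeric(n_steps + 1)
  out[1] <- x0
  x <- x0
  t <- 0
  for (k in seq_len(n_steps)) {
    k1 <- v(x, t)
    k2 <- v(x + dt * k1, t + dt)
    x <- x + dt * (k1 + k2) / 2
    t <- t + dt
    out[k + 1] <- x
  }
  out
}

#' Write a simulation result to CSV
#'
#' Columnar export with stable field names `day`, `rsa`, `edge`.
#'
#' @param sim A `scar_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sim <- function(sim, path) {
  data.table::fwrite(as.data.frame(sim), path)
  invisible(path)
}
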