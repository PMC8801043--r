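# FEM solver: fixed points, analytic and ODE oracles, convergence orders,
# RSA extraction and qualitative contraction behaviour.

test_that("equilibrium initial data stay at equilibrium for a year", {
  p <- scar_params()
  mesh <- scar_mesh(p, 101)
  sim <- scar_simulate(p, mesh, wounded = FALSE)
  expect_length(sim$rsa, 365)
  expect_lt(max(abs(sim$rsa - 1)), 1e-6)
  eq <- equilibrium_state(p, mesh)
  for (f in colnames(eq)) {
    scale <- max(abs(eq[, f]), 1)
    expect_lt(max(abs(sim$state[, f] - eq[, f])) / scale, 1e-6)
  }
})

test_that("no cell traction means no contraction", {
  p <- scar_params(xi = 0)
  sim <- scar_simulate(p, scar_mesh(p, 101))
  expect_equal(sim$rsa, rep(1, 365))
})

test_that("assembly is deterministic and solved by the equilibrium", {
  p <- scar_params()
  mesh <- scar_mesh(p, 51)
  eq <- equilibrium_state(p, mesh)
  s1 <- assemble_step(eq, eq, mesh, p, dt = 1)
  s2 <- assemble_step(eq, eq, mesh, p, dt = 1)
  expect_identical(s1$D, s2$D)
  expect_identical(s1$Up, s2$Up)
  expect_identical(s1$Lo, s2$Lo)
  expect_identical(s1$rhs, s2$rhs)
  res <- morphoscar:::system_residual(s1, eq)
  expect_lt(max(abs(res)), 1e-10)
})

test_that("pure diffusion reproduces the analytic single-mode decay", {
  days <- 20
  out <- run_diffusion_mode(n_nodes = 202, dt = 0.01, days = days)
  expected <- out$A * exp(-out$lambda * days)
  got <- unname(out$state[1, "c"])
  expect_equal(got / expected, 1, tolerance = 0.01)
  # the other fields are untouched by the degenerate configuration
  expect_equal(max(abs(out$state[, "v"])), 0)
  expect_equal(out$state[, "N"], rep(out$params$N_bar, 202))
})

test_that("homogeneous flux-free dynamics match a stiff ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- scar_params()
  n <- 61
  mesh <- scar_mesh(p, n)
  y0 <- c(c = 0.5 * p$c_w, N = 0.6 * p$N_bar, M = 0.1 * p$N_bar,
          rho = 0.5 * p$rho_bar)
  st <- scar_state(c = rep(y0[1], n), N = rep(y0[2], n), M = rep(y0[3], n),
                   rho = rep(y0[4], n), v = rep(0, n), eps = rep(0, n))
  dt <- 0.1
  days <- 36   # 360 backward-Euler steps
  ctrl <- scar_control(dt = dt, days = days, boundary = "closed")
  sim <- scar_simulate(p, mesh, ctrl, init = st)
  # the run must stay spatially homogeneous
  for (f in c("c", "N", "M", "rho")) {
    expect_lt(diff(range(sim$state[, f])),
              1e-8 * max(abs(sim$state[, f]), 1e-30))
  }
  ode <- deSolve::lsoda(y = unname(y0), times = c(0, days),
                        func = reaction_rhs_oracle, parms = p,
                        rtol = 1e-10, atol = 1e-14)
  ref <- ode[2, -1]
  scales <- c(p$c_w, p$N_bar, p$N_bar, p$rho_bar)
  for (i in 1:4) {
    rel <- abs(sim$state[1, i] - ref[i]) / max(abs(ref[i]), 1e-3 * scales[i])
    expect_lt(rel, 0.005)
  }
})

test_that("backward Euler converges with order at least one in time", {
  p <- scar_params()
  mesh <- scar_mesh(p, 101)
  rsa30 <- function(dt) {
    sim <- scar_simulate(p, mesh, scar_control(dt = dt, days = 30))
    sim$rsa[30]
  }
  r1 <- rsa30(1); r2 <- rsa30(0.5); r3 <- rsa30(0.25)
  e1 <- abs(r1 - r2)
  e2 <- abs(r2 - r3)
  order <- log2(e1 / e2)
  expect_gt(order, 0.8)
})

test_that("linear elements converge with order about two in space", {
  days <- 2
  err <- vapply(c(26, 51, 101), function(nn) {
    out <- run_diffusion_mode(n_nodes = nn, dt = 0.0025, days = days)
    x <- out$mesh$x
    exact <- function(xx) out$A * cos(pi * xx / 20) *
      exp(-out$lambda * days)
    mid <- (x[-1] + x[-length(x)]) / 2
    u_mid <- (out$state[-1, "c"] + out$state[-nrow(out$state), "c"]) / 2
    sqrt(sum(diff(x) * (u_mid - exact(mid))^2))
  }, 0.0)
  o1 <- log2(err[1] / err[2])
  o2 <- log2(err[2] / err[3])
  expect_gt(o1, 1.6); expect_lt(o1, 2.4)
  expect_gt(o2, 1.6); expect_lt(o2, 2.4)
})

test_that("a wounded run contracts, then retracts, and stays admissible", {
  p <- scar_params()
  sim <- scar_simulate(p, scar_mesh(p, 101))
  expect_true(all(sim$rsa > 0 & sim$rsa <= 1))
  expect_lt(which.min(sim$rsa), 365)
  expect_gt(sim$rsa[365], min(sim$rsa))
  expect_lte(sim$min_rsa, sim$last_rsa)
  # final state admissibility
  expect_true(all(sim$state[, c("c", "N", "M", "rho")] >= 0))
  expect_true(all(sim$state[, "eps"] < 1))
  expect_true(all(diff(sim$x) > 0))
})

test_that("stronger traction never weakens peak contraction", {
  mins <- vapply(c(1.5e-3, 3e-3, 4.5e-3), function(xi) {
    p <- scar_params(xi = xi)
    scar_simulate(p, scar_mesh(p, 101))$min_rsa
  }, 0.0)
  expect_true(all(diff(mins) <= 1e-10))
})

test_that("unstable parameter sets and Picard exhaustion raise errors", {
  p_bad <- scar_params(k_c = 1e-11)
  expect_false(p_bad$is_stable)
  expect_error(scar_simulate(p_bad, scar_mesh(p_bad, 51)), "stability")
  p <- scar_params()
  expect_error(
    scar_simulate(p, scar_mesh(p, 101),
                  scar_control(days = 10, picard_max = 1L)),
    "Picard")
})

test_that("RSA is the edge position relative to its initial value", {
  expect_equal(compute_rsa(rep(3, 10), 3), rep(1, 10))
  expect_equal(compute_rsa(1.5, 3), 0.5)
  expect_error(compute_rsa(c(1, -1), 2), "edge")
  expect_error(compute_rsa(1, 0), "positive")
})

test_that("edge advection matches the exponential closed form", {
  k <- 0.5
  traj <- advect_edge(2, function(x, t) -k * x, dt = 0.01, n_steps = 100)
  expect_equal(traj[101] / (2 * exp(-k)), 1, tolerance = 1e-3)
  expect_equal(traj[1], 2)
})

test_that("time_step leaves the equilibrium invariant in one sweep", {
  p <- scar_params()
  mesh <- scar_mesh(p, 51)
  eq <- equilibrium_state(p, mesh)
  st <- time_step(eq, mesh, p)
  expect_equal(attr(st, "iters"), 1L)
  expect_lt(max(abs(st[, "N"] - p$N_bar)) / p$N_bar, 1e-12)
  expect_lt(max(abs(st[, "v"])), 1e-12)
})

test_that("simulation results serialise to a stable columnar CSV", {
  p <- scar_params()
  sim <- scar_simulate(p, scar_mesh(p, 101),
                       scar_control(days = 40, snapshot_every = 20L))
  df <- as.data.frame(sim)
  expect_named(df, c("day", "rsa", "edge"))
  expect_equal(nrow(df), 40)
  tmp <- tempfile(fileext = ".csv")
  write_sim(sim, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$rsa, sim$rsa, tolerance = 1e-12)
  expect_length(sim$snapshots, 2)
  expect_equal(sim$snapshots[[1]]$day, 20)
})
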