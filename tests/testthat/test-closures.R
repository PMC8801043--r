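# Constitutive terms: signs, limits, equilibrium and determinism.

p0 <- scar_params()
mesh0 <- scar_mesh(p0, 51)
eq <- equilibrium_state(p0, mesh0)

test_that("homeostatic equilibrium is a fixed point of every closure", {
  R <- reaction_terms(eq, p0)
  for (z in names(R)) expect_equal(max(abs(R[[z]])), 0)
  J <- flux_terms(eq, p0, mesh0)
  for (z in names(J)) expect_equal(max(abs(J[[z]])), 0)
  sf <- stress_body_force(eq, p0, mesh0)
  expect_equal(max(abs(sf$sigma)), 0)
  expect_equal(max(abs(sf$f)), 0)
  expect_equal(max(abs(growth_term(eq, p0))), 0)
})

test_that("closures reject invalid states", {
  bad <- eq
  bad[3, "N"] <- -1
  expect_error(reaction_terms(bad, p0), "nonnegative")
  bad2 <- eq
  bad2[1, "eps"] <- 1.5
  expect_error(growth_term(bad2, p0), "strain")
})

test_that("secretion dominates decay for wound-like states", {
  n <- length(mesh0$x)
  st <- scar_state(c = rep(0.5 * p0$c_w, n), N = rep(0.2 * p0$N_bar, n),
                   M = rep(0.1 * p0$N_bar, n),
                   rho = rep(0.2 * p0$rho_bar, n),
                   v = rep(0, n), eps = rep(0, n))
  R <- reaction_terms(st, p0)
  expect_true(all(R$c > 0))
})

test_that("secretion is linear in c far below saturation", {
  p <- scar_params(delta_c = 1e-12)   # decay negligible against secretion
  n <- length(mesh0$x)
  mk <- function(cc) scar_state(c = rep(cc, n), N = rep(p$N_bar, n),
                                M = rep(0.1 * p$N_bar, n),
                                rho = rep(p$rho_bar, n),
                                v = rep(0, n), eps = rep(0, n))
  c_small <- 1e-4 * p$a_c_II
  r1 <- reaction_terms(mk(c_small), p)$c[1]
  r2 <- reaction_terms(mk(2 * c_small), p)$c[1]
  expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("fluxes are Fickian for c, density-dependent for cells, zero for collagen", {
  n <- length(mesh0$x)
  # spatially constant state: all fluxes vanish
  st_const <- scar_state(c = rep(0.3 * p0$c_w, n), N = rep(p0$N_bar, n),
                         M = rep(100, n), rho = rep(p0$rho_bar, n),
                         v = rep(0, n), eps = rep(0, n))
  J <- flux_terms(st_const, p0, mesh0)
  for (z in names(J)) expect_equal(max(abs(J[[z]])), 0)
  # linear c profile: J_c = -D * slope, constant in x
  slope <- p0$c_w / p0$domain_length
  st_lin <- scar_state(c = slope * mesh0$x, N = rep(p0$N_bar, n),
                       M = rep(0, n), rho = rep(p0$rho_bar, n),
                       v = rep(0, n), eps = rep(0, n))
  J <- flux_terms(st_lin, p0, mesh0)
  expect_equal(J$c, rep(-p0$D_c * slope, n))
  expect_equal(J$rho, rep(0, n))
  # cell flux magnitude grows with total cell density
  mkN <- function(scale) {
    scar_state(c = rep(0, n), N = scale * p0$N_bar * (1 + mesh0$x / 10),
               M = rep(0.1 * scale * p0$N_bar, n), rho = rep(p0$rho_bar, n),
               v = rep(0, n), eps = rep(0, n))
  }
  J1 <- flux_terms(mkN(1), p0, mesh0)
  J2 <- flux_terms(mkN(2), p0, mesh0)
  expect_true(all(abs(J2$N[2:(n - 1)]) > abs(J1$N[2:(n - 1)])))
})

test_that("stress and body force behave as the closure dictates", {
  n <- length(mesh0$x)
  # no myofibroblasts -> no traction force
  st <- scar_state(c = rep(0, n), N = rep(p0$N_bar, n), M = rep(0, n),
                   rho = p0$rho_bar * (1 + 0.3 * sin(mesh0$x)),
                   v = rep(0, n), eps = rep(0.1, n))
  sf <- stress_body_force(st, p0, mesh0)
  expect_equal(max(abs(sf$f)), 0)
  # static state, uniform strain and collagen: uniform stress, zero gradient
  st_u <- scar_state(c = rep(0, n), N = rep(p0$N_bar, n), M = rep(0, n),
                     rho = rep(p0$rho_bar, n), v = rep(0, n),
                     eps = rep(0.2, n))
  sf_u <- stress_body_force(st_u, p0, mesh0)
  expect_equal(sf_u$sigma,
               rep(p0$E_mod * sqrt(p0$rho_bar) * 0.2, n))
  expect_equal(diff(sf_u$sigma), rep(0, n - 1))
})

test_that("plastic growth needs myofibroblasts, signalling and strain", {
  n <- length(mesh0$x)
  mk <- function(cc, M, ep, zeta = p0$zeta) {
    list(state = scar_state(c = rep(cc, n), N = rep(p0$N_bar, n),
                            M = rep(M, n), rho = rep(p0$rho_bar, n),
                            v = rep(0, n), eps = rep(ep, n)),
         params = scar_params(zeta = zeta))
  }
  g <- function(x) growth_term(x$state, x$params)
  expect_equal(max(abs(g(mk(0.5 * p0$c_w, 0, 0.2)))), 0)     # M = 0
  expect_equal(max(abs(g(mk(0, 500, 0.2)))), 0)              # c = 0
  expect_equal(max(abs(g(mk(0.5 * p0$c_w, 500, 0)))), 0)     # eps = 0
  g1 <- g(mk(0.5 * p0$c_w, 500, 0.2, zeta = 1e-4))
  g2 <- g(mk(0.5 * p0$c_w, 500, 0.2, zeta = 2e-4))
  expect_equal(g2, 2 * g1)
  expect_true(all(g1 > 0))   # positive G relaxes eps: strain becomes permanent
})

test_that("closure evaluation is deterministic", {
  st <- initial_state(p0, mesh0)
  expect_identical(reaction_terms(st, p0), reaction_terms(st, p0))
  expect_identical(flux_terms(st, p0, mesh0), flux_terms(st, p0, mesh0))
})
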