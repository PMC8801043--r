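# Shared fixtures (memoised across test files) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small solver corpus used by dataset/metrics/montecarlo tests
fixture_corpus <- function() {
  memo("corpus24", generate_corpus(24, mesh = scar_mesh(10, 101),
                                   master_seed = 42L))
}

fixture_split <- function() {
  memo("split24", split_and_scale(fixture_corpus(), n_folds = 4, seed = 9L))
}

# a quickly trained surrogate (not accurate; structural fixture)
fixture_model <- function() {
  memo("model24", scar_surrogate(fixture_split(), max_epochs = 60L,
                                 seed = 5L))
}

# synthetic, trivially learnable multi-target regression data in (0, 1]
synthetic_xy <- function(n, d_in = 25L, d_out = 365L, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(n * d_in), n, d_in)
  tt <- seq(0, 1, length.out = d_out)
  Y <- t(vapply(seq_len(n), function(i) {
    depth <- 0.2 + 0.6 * X[i, 1]
    when <- 0.1 + 0.5 * X[i, 2]
    width <- 0.05 + 0.2 * X[i, 3]
    rsa <- 1 - depth * exp(-((tt - when) / width)^2)
    pmin(pmax(rsa, 1e-3), 1)
  }, numeric(d_out)))
  list(X = X, Y = Y)
}

# independent 0-D oracle: the reaction system written out by hand
# (kept deliberately separate from the package's closure code)
reaction_rhs_oracle <- function(t, y, p) {
  c_ <- y[1]; N <- y[2]; M <- y[3]; rho <- y[4]
  cellsI <- N + p$eta_I * M
  crowd <- 1 - p$kappa_F * (N + M)
  enh <- c_ / (p$a_c_I + c_)
  dc <- p$k_c * c_ / (p$a_c_II + c_) * cellsI - p$delta_c * cellsI * rho * c_
  dN <- p$r_F * (1 + p$r_F_max * enh) * crowd * N - p$k_F * c_ * N -
    p$delta_N * N
  dM <- p$r_F * (1 + p$r_F_max) * enh * crowd * M + p$k_F * c_ * N -
    p$delta_M * M
  drho <- p$k_rho * (1 + p$k_rho_max * c_ / (p$a_c_IV + c_)) *
    (N + p$eta_II * M) - p$delta_rho * cellsI * rho
  list(c(dc, dN, dM, drho))
}

# parameter set with every coupling switched off except signalling diffusion
diffusion_only_params <- function(D = 1) {
  scar_params(D_c = D, D_F = 0, chi_F = 0, r_F = 0, r_F_max = 0, k_F = 0,
              delta_N = 0, delta_M = 0, k_c = 0, delta_c = 0, k_rho = 0,
              k_rho_max = 0, xi = 0, zeta = 0, eta_I = 0, eta_II = 0)
}

# single-mode diffusion run: initial c = A cos(pi x / (2 X)) decaying as
# exp(-D (pi/(2X))^2 t); far-field Dirichlet c = 0 holds exactly at x = X
run_diffusion_mode <- function(n_nodes, dt, days, A = 1e-9) {
  p <- diffusion_only_params()
  mesh <- scar_mesh(p, n_nodes)
  X <- p$domain_length
  st <- scar_state(c = A * cos(pi * mesh$x / (2 * X)),
                   N = rep(p$N_bar, n_nodes), M = rep(0, n_nodes),
                   rho = rep(p$rho_bar, n_nodes), v = rep(0, n_nodes),
                   eps = rep(0, n_nodes))
  ctrl <- scar_control(dt = dt, days = days)
  sim <- scar_simulate(p, mesh, ctrl, init = st)
  list(params = p, mesh = mesh, state = sim$state, A = A,
       lambda = p$D_c * (pi / (2 * X))^2)
}
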