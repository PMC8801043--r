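# Feed-forward network internals: initialisation, forward/backward passes
# and the first-order optimizers used by the learning-rate range test.
# Written in plain matrix code; the network is small enough (49,365 weights)
# that BLAS-backed R is entirely adequate.

relu <- function(x) (x > 0) * x

# pre-activations clamped so the output stays strictly inside (0, 1) in
# double precision
sigmoid <- function(x) 1 / (1 + exp(pmin(pmax(-x, -30), 30)))

#' Build an untrained surrogate network
#'
#' Two rectified-linear hidden layers and a sigmoid output layer (the RSA is
#' bounded in (0, 1)). Hidden weights use seeded He-normal initialisation,
#' the output layer Glorot-uniform.
#'
#' @param input Number of input features (default 25).
#' @param hidden Sizes of the two hidden layers (default `c(100, 100)`).
#' @param output Number of output units (default 365, one per simulated
#'   day).
#' @param seed Integer seed for the weight initialisation.
#' @return A list with weight matrices `W`, bias vectors `b` and the layer
#'   configuration; class `scar_network`.
#' @export
build_network <- function(input = 25L, hidden = c(100L, 100L), output = 365L,
                          seed = 1L) {
  sizes <- c(input, hidden, output)
  if (any(sizes < 1)) stop("all layer sizes must be positive", call. = FALSE)
  with_seed(seed, {
    W <- list()
    b <- list()
    nl <- length(sizes) - 1L
    for (l in seq_len(nl)) {
      fan_in <- sizes[l]
      fan_out <- sizes[l + 1L]
      if (l < nl) {            # He normal for the rectified-linear layers
        W[[l]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
                         fan_in, fan_out)
      } else {                 # Glorot uniform for the sigmoid output
        lim <- sqrt(6 / (fan_in + fan_out))
        W[[l]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim),
                         fan_in, fan_out)
      }
      b[[l]] <- numeric(fan_out)
    }
    structure(list(W = W, b = b, sizes = sizes, seed = seed),
              class = "scar_network")
  })
}

#' Number of learnable parameters of a network
#'
#' @param net A `scar_network` (or a fitted `scar_surrogate`).
#' @return Integer count of weights plus biases.
#' @export
n_parameters <- function(net) {
  if (inherits(net, "scar_surrogate")) net <- net$net
  sum(vapply(net$W, length, 0L)) + sum(vapply(net$b, length, 0L))
}

# forward pass; keeps layer activations for backprop
net_forward <- function(net, X) {
  A1 <- relu(X %*% net$W[[1]] + rep(net$b[[1]], each = nrow(X)))
  A2 <- relu(A1 %*% net$W[[2]] + rep(net$b[[2]], each = nrow(A1)))
  Yh <- sigmoid(A2 %*% net$W[[3]] + rep(net$b[[3]], each = nrow(A2)))
  list(A1 = A1, A2 = A2, Yh = Yh)
}

# gradients of the mean-squared-error loss over all entries of the batch
net_backward <- function(net, X, Y, fw) {
  nN <- length(Y)
  d3 <- (2 / nN) * (fw$Yh - Y) * fw$Yh * (1 - fw$Yh)
  gW3 <- crossprod(fw$A2, d3)
  gb3 <- colSums(d3)
  d2 <- (d3 %*% t(net$W[[3]])) * (fw$A2 > 0)
  gW2 <- crossprod(fw$A1, d2)
  gb2 <- colSums(d2)
  d1 <- (d2 %*% t(net$W[[2]])) * (fw$A1 > 0)
  gW1 <- crossprod(X, d1)
  gb1 <- colSums(d1)
  list(W = list(gW1, gW2, gW3), b = list(gb1, gb2, gb3))
}

mse_loss <- function(Y, Yh) mean((Y - Yh)^2)

# ---- optimizers -------------------------------------------------------------
# Each optimizer is a closure holding its slot variables; update() maps
# (parameter list, gradient list, step counter, learning rate) to the new
# parameter list. theta/grad are flat lists of arrays.

.optimizer_names <- c("sgd", "adagrad", "adadelta", "rmsprop", "adam",
                      "adamax", "nadam")

make_optimizer <- function(name) {
  name <- match.arg(tolower(name), .optimizer_names)
  e <- new.env(parent = emptyenv())
  zeros_like <- function(th) lapply(th, function(x) array(0, dim = dim(x) %||% length(x)))
  eps <- 1e-8
  step <- switch(name,
    sgd = function(th, g, t, lr) {
      Map(function(p, gg) p - lr * gg, th, g)
    },
    adagrad = function(th, g, t, lr) {
      if (is.null(e$G)) e$G <- zeros_like(th)
      e$G <- Map(function(G, gg) G + gg^2, e$G, g)
      Map(function(p, gg, G) p - lr * gg / (sqrt(G) + eps), th, g, e$G)
    },
    adadelta = function(th, g, t, lr) {
      rho <- 0.95
      if (is.null(e$Eg)) { e$Eg <- zeros_like(th); e$Ed <- zeros_like(th) }
      e$Eg <- Map(function(E, gg) rho * E + (1 - rho) * gg^2, e$Eg, g)
      d <- Map(function(E, Ed, gg) -sqrt(Ed + eps) / sqrt(E + eps) * gg,
               e$Eg, e$Ed, g)
      e$Ed <- Map(function(Ed, dd) rho * Ed + (1 - rho) * dd^2, e$Ed, d)
      Map(function(p, dd) p + lr * dd, th, d)
    },
    rmsprop = function(th, g, t, lr) {
      if (is.null(e$Eg)) e$Eg <- zeros_like(th)
      e$Eg <- Map(function(E, gg) 0.9 * E + 0.1 * gg^2, e$Eg, g)
      Map(function(p, gg, E) p - lr * gg / (sqrt(E) + eps), th, g, e$Eg)
    },
    adam = function(th, g, t, lr) {
      b1 <- 0.9; b2 <- 0.999
      if (is.null(e$m)) { e$m <- zeros_like(th); e$v <- zeros_like(th) }
      e$m <- Map(function(m, gg) b1 * m + (1 - b1) * gg, e$m, g)
      e$v <- Map(function(v, gg) b2 * v + (1 - b2) * gg^2, e$v, g)
      c1 <- 1 - b1^t; c2 <- 1 - b2^t
      Map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
          th, e$m, e$v)
    },
    adamax = function(th, g, t, lr) {
      b1 <- 0.9; b2 <- 0.999
      if (is.null(e$m)) { e$m <- zeros_like(th); e$u <- zeros_like(th) }
      e$m <- Map(function(m, gg) b1 * m + (1 - b1) * gg, e$m, g)
      e$u <- Map(function(u, gg) pmax(b2 * u, abs(gg)), e$u, g)
      c1 <- 1 - b1^t
      Map(function(p, m, u) p - (lr / c1) * m / (u + eps), th, e$m, e$u)
    },
    nadam = function(th, g, t, lr) {
      b1 <- 0.9; b2 <- 0.999
      if (is.null(e$m)) { e$m <- zeros_like(th); e$v <- zeros_like(th) }
      e$m <- Map(function(m, gg) b1 * m + (1 - b1) * gg, e$m, g)
      e$v <- Map(function(v, gg) b2 * v + (1 - b2) * gg^2, e$v, g)
      c1 <- 1 - b1^t; c2 <- 1 - b2^t
      Map(function(p, m, gg, v) {
        mh <- b1 * m / c1 + (1 - b1) * gg / c1
        p - lr * mh / (sqrt(v / c2) + eps)
      }, th, e$m, g, e$v)
    })
  list(name = name, step = step)
}

# flatten/unflatten network parameters for the optimizer
net_params <- function(net) c(net$W, net$b)
net_set_params <- function(net, th) {
  nl <- length(net$W)
  net$W <- th[seq_len(nl)]
  net$b <- lapply(th[nl + seq_len(nl)], as.numeric)
  net
}
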