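# Surrogate fitting: training loop with learning-rate decay and early
# stopping, the S3 model object and its methods.

#' Early-stopping bookkeeping
#'
#' Given a sequence of monitored losses, finds the epoch after which
#' training halts: an epoch counts as an improvement only if it undercuts
#' the best loss so far by more than `min_delta`; training stops once
#' `patience` consecutive epochs bring no improvement.
#'
#' @param losses Numeric vector of per-epoch monitored losses.
#' @param patience Number of non-improving epochs tolerated (default 30).
#' @param min_delta Minimum decrease that counts as improvement (default
#'   `1e-5`).
#' @return List with `stop_epoch` (last epoch trained, `length(losses)` if
#'   the patience was never exhausted) and `best_epoch` (epoch whose weights
#'   are restored).
#' @export
early_stopping <- function(losses, patience = 30L, min_delta = 1e-5) {
  stopifnot(patience >= 1, min_delta >= 0)
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  for (ep in seq_along(losses)) {
    if (best - losses[ep] > min_delta) {
      best <- losses[ep]
      best_epoch <- ep
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) {
        return(list(stop_epoch = ep, best_epoch = best_epoch))
      }
    }
  }
  list(stop_epoch = length(losses), best_epoch = best_epoch)
}

# core training loop shared by scar_surrogate() and lr_range_test()
train_network <- function(net, X, Y, X_val = NULL, Y_val = NULL,
                          optimizer = "adamax", lr = 0.015, decay = 0.99,
                          batch_size = 64L, patience = 30L, min_delta = 1e-5,
                          max_epochs = 2000L, seed = 1L,
                          early_stop = TRUE, verbose = FALSE) {
  opt <- make_optimizer(optimizer)
  th <- net_params(net)
  n <- nrow(X)
  monitored <- train_hist <- val_hist <- lr_hist <- numeric(0)
  best <- Inf
  best_epoch <- 0L
  best_th <- th
  wait <- 0L
  t_step <- 0L
  stopped <- max_epochs
  for (epoch in seq_len(max_epochs)) {
    lr_t <- lr * decay^(epoch - 1)
    ord <- with_seed(seed + epoch, sample.int(n))
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      net <- net_set_params(net, th)
      fw <- net_forward(net, Xb)
      gr <- net_backward(net, Xb, Yb, fw)
      t_step <- t_step + 1L
      th <- opt$step(th, c(gr$W, gr$b), t_step, lr_t)
    }
    net <- net_set_params(net, th)
    tl <- mse_loss(Y, net_forward(net, X)$Yh)
    vl <- if (!is.null(X_val)) mse_loss(Y_val, net_forward(net, X_val)$Yh)
          else NA_real_
    mon <- if (!is.null(X_val)) vl else tl
    train_hist <- c(train_hist, tl)
    val_hist <- c(val_hist, vl)
    lr_hist <- c(lr_hist, lr_t)
    monitored <- c(monitored, mon)
    if (!is.finite(mon)) {
      stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
           call. = FALSE)
    }
    if (verbose && epoch %% 25 == 0) {
      message(sprintf("epoch %4d  loss %.3e  lr %.4g", epoch, mon, lr_t))
    }
    # early-stopping bookkeeping (same rule as early_stopping())
    if (best - mon > min_delta) {
      best <- mon
      best_epoch <- epoch
      best_th <- th
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (early_stop && wait >= patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  if (early_stop && best_epoch > 0L) th <- best_th
  net <- net_set_params(net, th)
  list(net = net,
       history = data.frame(epoch = seq_along(monitored), lr = lr_hist,
                            train_loss = train_hist, val_loss = val_hist,
                            monitored = monitored),
       best_epoch = if (best_epoch > 0L) best_epoch else stopped,
       stop_epoch = stopped)
}

#' Fit the neural surrogate for the RSA course
#'
#' Trains a 25-100-100-365 feed-forward network (rectified-linear hidden
#' layers, sigmoid output) to map scaled patient/wound parameters to the
#' 365-day relative-surface-area course, minimising mean squared error with
#' the Adamax optimizer, a multiplicative learning-rate decay per epoch and
#' early stopping with best-weight restoration.
#'
#' @param x Training inputs: a `scar_split` (recommended; supplies scaled
#'   inputs, targets and the attached scaler) or a raw/scaled numeric
#'   matrix.
#' @param y Target matrix (ignored when `x` is a `scar_split`).
#' @param validation Optional list `list(x =, y =)` monitored for early
#'   stopping instead of the training loss (inputs on the same scale as
#'   `x`).
#' @param optimizer One of `"sgd"`, `"adagrad"`, `"adadelta"`, `"rmsprop"`,
#'   `"adam"`, `"adamax"` (default), `"nadam"`.
#' @param lr Initial learning rate (default 0.015).
#' @param decay Per-epoch multiplicative learning-rate decay (default 0.99).
#' @param batch_size Minibatch size (default 64).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param min_delta Improvement threshold on the monitored loss (default
#'   `1e-5`).
#' @param max_epochs Hard cap on epochs (default 2000; early stopping
#'   normally halts far sooner).
#' @param hidden Hidden layer sizes (default `c(100, 100)`).
#' @param seed Integer seed (weights and batch shuffling).
#' @param scaler Optional `scar_scaler` to attach when `x` is a matrix of
#'   raw inputs.
#' @param early_stop Disable to always run `max_epochs` epochs.
#' @param verbose Print progress.
#' @return Object of class `scar_surrogate` with the trained network,
#'   training history, attached scaler and the data used for fitting.
#' @export
scar_surrogate <- function(x, y = NULL, validation = NULL,
                           optimizer = "adamax", lr = 0.015, decay = 0.99,
                           batch_size = 64L, patience = 30L,
                           min_delta = 1e-5, max_epochs = 2000L,
                           hidden = c(100L, 100L), seed = 1L, scaler = NULL,
                           early_stop = TRUE, verbose = FALSE) {
  if (inherits(x, "scar_split")) {
    scaler <- x$scaler
    y <- x$Y_train
    x <- x$Xs_train
  }
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y need matching rows", call. = FALSE)
  if (any(y <= 0) || any(y > 1)) {
    stop("targets must lie in (0, 1] (RSA values)", call. = FALSE)
  }
  net <- build_network(input = ncol(x), hidden = hidden, output = ncol(y),
                       seed = seed)
  fit <- train_network(net, x, y,
                       X_val = validation$x, Y_val = validation$y,
                       optimizer = optimizer, lr = lr, decay = decay,
                       batch_size = batch_size, patience = patience,
                       min_delta = min_delta, max_epochs = max_epochs,
                       seed = seed, early_stop = early_stop,
                       verbose = verbose)
  structure(list(net = fit$net, history = fit$history,
                 best_epoch = fit$best_epoch, stop_epoch = fit$stop_epoch,
                 optimizer = optimizer, lr = lr, decay = decay,
                 batch_size = batch_size, patience = patience,
                 min_delta = min_delta, seed = seed, scaler = scaler,
                 x = x, y = y),
            class = "scar_surrogate")
}

#' Predict RSA courses from the surrogate
#'
#' Applies the attached Min-Max scaler (when `newdata` is on the raw
#' parameter scale) and evaluates the network in one batched pass. Inputs
#' outside the scaler's fitted range trigger a warning, not an error.
#'
#' @param object A fitted `scar_surrogate`.
#' @param newdata Matrix (or vector) of inputs, one row per case.
#' @param scaled Set `TRUE` when `newdata` is already Min-Max scaled.
#' @param ... Unused.
#' @return Matrix of predicted RSA courses (rows = cases, columns = days),
#'   all values strictly inside (0, 1).
#' @export
predict.scar_surrogate <- function(object, newdata, scaled = FALSE, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$net$sizes[1]) {
    stop(sprintf("newdata has %d columns; the network expects %d",
                 ncol(newdata), object$net$sizes[1]), call. = FALSE)
  }
  z <- if (scaled || is.null(object$scaler)) newdata
       else scale_features(object$scaler, newdata)
  net_forward(object$net, z)$Yh
}

#' @export
fitted.scar_surrogate <- function(object, ...) {
  net_forward(object$net, object$x)$Yh
}

#' @export
residuals.scar_surrogate <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
coef.scar_surrogate <- function(object, ...) {
  list(W = object$net$W, b = object$net$b)
}

#' @export
print.scar_surrogate <- function(x, ...) {
  cat("Feed-forward RSA surrogate\n")
  cat(sprintf("  architecture %s (%s hidden units, sigmoid output), %d parameters\n",
              paste(x$net$sizes, collapse = "-"), "rectified-linear",
              n_parameters(x$net)))
  cat(sprintf("  optimizer %s, lr %.4g (decay %.3g), batch %d\n",
              x$optimizer, x$lr, x$decay, x$batch_size))
  cat(sprintf("  trained %d epochs (best epoch %d), final monitored MSE %.3e\n",
              x$stop_epoch, x$best_epoch,
              x$history$monitored[x$best_epoch]))
  invisible(x)
}

#' @export
summary.scar_surrogate <- function(object, ...) {
  print(object)
  tr <- fitted(object)
  cat(sprintf("  training R^2 %.4f, MSE %.3e (n = %d)\n",
              r_squared(object$y, tr), mse_loss(object$y, tr),
              nrow(object$x)))
  invisible(object)
}

#' @export
plot.scar_surrogate <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "MSE loss", ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Serialise a fitted surrogate to a portable container
#'
#' Writes weights, layer configuration, scaler parameters and the training
#' history as a single JSON file (text, portable across platforms).
#'
#' @param model A `scar_surrogate`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  obj <- list(sizes = model$net$sizes,
              W = lapply(model$net$W, unclass),
              b = model$net$b,
              scaler = if (!is.null(model$scaler)) unclass(model$scaler),
              history = model$history,
              meta = list(optimizer = model$optimizer, lr = model$lr,
                          decay = model$decay, batch_size = model$batch_size,
                          patience = model$patience,
                          min_delta = model$min_delta, seed = model$seed,
                          best_epoch = model$best_epoch,
                          stop_epoch = model$stop_epoch))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a surrogate written by [write_surrogate()]
#'
#' @param path JSON container path.
#' @return A `scar_surrogate` (without the training data).
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(W = lapply(obj$W, as.matrix),
                        b = lapply(obj$b, as.numeric),
                        sizes = as.integer(obj$sizes),
                        seed = obj$meta$seed),
                   class = "scar_network")
  scaler <- if (!is.null(obj$scaler)) {
    structure(list(min = unlist(obj$scaler$min), max = unlist(obj$scaler$max)),
              class = "scar_scaler")
  }
  structure(list(net = net, history = obj$history,
                 best_epoch = obj$meta$best_epoch,
                 stop_epoch = obj$meta$stop_epoch,
                 optimizer = obj$meta$optimizer, lr = obj$meta$lr,
                 decay = obj$meta$decay, batch_size = obj$meta$batch_size,
                 patience = obj$meta$patience,
                 min_delta = obj$meta$min_delta, seed = obj$meta$seed,
                 scaler = scaler, x = NULL, y = NULL),
            class = "scar_surrogate")
}

#' Learning-rate range test across optimizers
#'
#' Trains a fresh network for each (optimizer, learning rate) combination
#' for a fixed number of epochs without early stopping and records the
#' moving-average-smoothed final training loss. Divergence (non-finite
#' loss) is recorded as a failure, never raised.
#'
#' @param x Training inputs (scaled matrix or `scar_split`).
#' @param y Targets (ignored for a `scar_split`).
#' @param optimizers Character vector of at least one optimizer name.
#' @param lrs Numeric grid of learning rates in `[1e-4, 1]`.
#' @param epochs Training epochs per cell (default 150).
#' @param batch_size Minibatch size (default 64).
#' @param smooth Moving-average window (epochs) for the recorded loss.
#' @param seed Integer seed (same initial weights for every cell).
#' @param verbose Print one line per cell.
#' @return A data.frame (class `lr_range_table`) with columns `optimizer`,
#'   `lr`, `loss` and `diverged`, sorted by loss (failures last).
#' @export
lr_range_test <- function(x, y = NULL, optimizers = c("adamax", "adam"),
                          lrs = 10^seq(-4, 0, length.out = 9),
                          epochs = 150L, batch_size = 64L, smooth = 5L,
                          seed = 1L, verbose = FALSE) {
  if (inherits(x, "scar_split")) {
    y <- x$Y_train
    x <- x$Xs_train
  }
  if (length(optimizers) < 1 || length(lrs) < 1) {
    stop("need at least one optimizer and one learning rate", call. = FALSE)
  }
  optimizers <- vapply(optimizers, function(o) {
    match.arg(tolower(o), .optimizer_names)
  }, "")
  grid <- expand.grid(optimizer = optimizers, lr = lrs,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    o <- grid$optimizer[i]
    l <- grid$lr[i]
    net <- build_network(input = ncol(x), output = ncol(y), seed = seed)
    out <- tryCatch(
      train_network(net, x, y, optimizer = o, lr = l, decay = 1,
                    batch_size = batch_size, max_epochs = epochs,
                    seed = seed, early_stop = FALSE),
      error = function(e) NULL)
    loss <- NA_real_
    if (!is.null(out)) {
      tl <- out$history$train_loss
      k <- min(smooth, length(tl))
      sm <- stats::filter(tl, rep(1 / k, k), sides = 1)
      loss <- as.numeric(sm[length(tl)])
    }
    diverged <- is.null(out) || !is.finite(loss)
    if (verbose) {
      message(sprintf("%-8s lr %.4g -> %s", o, l,
                      if (diverged) "diverged" else sprintf("%.3e", loss)))
    }
    data.frame(optimizer = o, lr = l,
               loss = if (diverged) NA_real_ else loss, diverged = diverged)
  })
  tab <- do.call(rbind, res)
  tab <- tab[order(tab$diverged, tab$loss), ]
  rownames(tab) <- NULL
  class(tab) <- c("lr_range_table", "data.frame")
  tab
}

#' @export
plot.lr_range_table <- function(x, ...) {
  ok <- x[!x$diverged, ]
  graphics::plot(NA, xlim = range(x$lr), ylim = range(ok$loss), log = "xy",
                 xlab = "learning rate", ylab = "smoothed MSE loss", ...)
  for (o in unique(ok$optimizer)) {
    d <- ok[ok$optimizer == o, ]
    d <- d[order(d$lr), ]
    graphics::lines(d$lr, d$loss, type = "b",
                    col = match(o, unique(ok$optimizer)))
  }
  graphics::legend("bottomleft", unique(ok$optimizer),
                   col = seq_along(unique(ok$optimizer)), lty = 1, bty = "n")
  invisible(x)
}
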