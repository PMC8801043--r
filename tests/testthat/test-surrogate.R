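# Network construction, training protocol, early stopping and prediction.

test_that("the network has the stated architecture and parameter count", {
  net <- build_network(seed = 1L)
  expect_equal(net$sizes, c(25, 100, 100, 365))
  expect_equal(n_parameters(net),
               25 * 100 + 100 + 100 * 100 + 100 + 100 * 365 + 365)
  expect_equal(n_parameters(net), 49565)
})

test_that("forward passes respect the sigmoid output range", {
  net <- build_network(seed = 2L)
  y0 <- morphoscar:::net_forward(net, matrix(0, 1, 25))$Yh
  expect_equal(dim(y0), c(1, 365))
  expect_true(all(y0 > 0 & y0 < 1))
  # extreme inputs saturate but never leave the open interval
  yext <- morphoscar:::net_forward(net, matrix(c(-1e3, 1e3), 2, 25))$Yh
  expect_true(all(yext > 0 & yext < 1))
})

test_that("initialisation is deterministic given the seed", {
  x <- matrix(runif(3 * 25), 3, 25)
  n1 <- build_network(seed = 7L)
  n2 <- build_network(seed = 7L)
  expect_identical(morphoscar:::net_forward(n1, x)$Yh,
                   morphoscar:::net_forward(n2, x)$Yh)
  n3 <- build_network(seed = 8L)
  expect_false(identical(morphoscar:::net_forward(n1, x)$Yh,
                         morphoscar:::net_forward(n3, x)$Yh))
})

test_that("early-stopping bookkeeping follows the patience/threshold rule", {
  # steady improvement: never stops early
  out <- early_stopping(seq(1, 0.1, by = -0.1) * 1e-1, patience = 3)
  expect_equal(out$stop_epoch, 10)
  expect_equal(out$best_epoch, 10)
  # plateau: halts within patience + 1 epochs of the plateau start
  losses <- c(seq(0.5, 0.1, length.out = 10), rep(0.1, 60))
  out <- early_stopping(losses, patience = 30)
  expect_equal(out$best_epoch, 10)
  expect_lte(out$stop_epoch, 10 + 31)
  expect_equal(out$stop_epoch, 40)
  # sub-threshold decreases do not count as improvement
  creeping <- 0.5 - 1e-6 * seq_len(50)
  out <- early_stopping(creeping, patience = 5, min_delta = 1e-5)
  expect_equal(out$best_epoch, 1)
  expect_equal(out$stop_epoch, 6)
  expect_error(early_stopping(creeping, patience = 0), "patience")
})

test_that("training reduces the loss on a synthetic corpus", {
  d <- synthetic_xy(200, seed = 4L)
  m <- scar_surrogate(d$X, d$Y, max_epochs = 25L, seed = 3L)
  h <- m$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_s3_class(m, "scar_surrogate")
})

test_that("training halts within patience + 1 epochs of a loss plateau", {
  # tiny easily saturated problem: loss flattens quickly, the stop epoch
  # must then trail the best epoch by exactly the patience
  d <- synthetic_xy(30, seed = 6L)
  m <- scar_surrogate(d$X, d$Y, patience = 5L, min_delta = 1e-3,
                      max_epochs = 500L, seed = 3L)
  expect_lt(m$stop_epoch, 500L)
  expect_equal(m$stop_epoch, m$best_epoch + 5L)
})

test_that("the network can memorise a small sample set", {
  d <- synthetic_xy(10, seed = 5L)
  m <- scar_surrogate(d$X, d$Y, decay = 1, max_epochs = 1500L,
                      early_stop = FALSE, seed = 11L)
  yh <- fitted(m)
  expect_gt(r_squared(d$Y, yh), 0.999)
  expect_lt(max(abs(yh - d$Y)), 0.01)
  expect_lt(max(abs(residuals(m))), 0.01)
})

test_that("divergent training raises an error naming the epoch", {
  # a non-finite input poisons the forward pass: the monitored loss goes
  # NaN and the guard must name the epoch
  d <- synthetic_xy(50, seed = 8L)
  Xbad <- d$X
  Xbad[1, 1] <- Inf
  expect_error(
    scar_surrogate(Xbad, d$Y, max_epochs = 10L, seed = 1L),
    "diverged.*epoch")
})

test_that("prediction is batched, shape-checked and range-guarded", {
  m <- fixture_model()
  X <- fixture_split()$X_test
  yh <- predict(m, X)
  expect_equal(dim(yh), c(nrow(X), 365))
  expect_true(all(yh > 0 & yh < 1))
  yh1 <- predict(m, X[1, ])
  expect_equal(dim(yh1), c(1, 365))
  expect_error(predict(m, X[, 1:10]), "columns")
  # out-of-range inputs warn (extrapolation), not error
  Xout <- X
  Xout[1, 1] <- m$scaler$max[1] * 2
  expect_warning(predict(m, Xout), "range")
})

test_that("a surrogate round-trips through its serialised container", {
  m <- fixture_model()
  tmp <- tempfile(fileext = ".json")
  write_surrogate(m, tmp)
  m2 <- read_surrogate(tmp)
  X <- fixture_split()$X_test
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$best_epoch, m$best_epoch)
})

test_that("the learning-rate range test records a full grid with failures flagged", {
  d <- synthetic_xy(60, seed = 9L)
  # one-cell grid
  t1 <- lr_range_test(d$X, d$Y, optimizers = "adamax", lrs = 0.01,
                      epochs = 3L, seed = 1L)
  expect_equal(nrow(t1), 1L)
  expect_false(t1$diverged)
  # divergence is recorded per cell, never raised
  dbad <- d$X
  dbad[1, 1] <- Inf
  tbad <- lr_range_test(dbad, d$Y, optimizers = "adamax",
                        lrs = c(0.005, 0.05), epochs = 2L, seed = 1L)
  expect_true(all(tbad$diverged))
  expect_true(all(is.na(tbad$loss)))
  # full grid over two optimizers; failures sort last, finite losses ascend
  t2 <- lr_range_test(d$X, d$Y, optimizers = c("sgd", "adamax"),
                      lrs = c(0.005, 0.9), epochs = 3L, seed = 1L)
  expect_equal(nrow(t2), 4L)
  ok <- t2[!t2$diverged, ]
  expect_true(all(diff(ok$loss) >= 0))
  # a large learning rate cannot beat the optimizer's own grid best
  sgd <- t2[t2$optimizer == "sgd", ]
  big <- sgd$loss[sgd$lr == max(sgd$lr)]
  expect_true(is.na(big) || big >= min(sgd$loss, na.rm = TRUE))
  expect_error(lr_range_test(d$X, d$Y, optimizers = character(0)),
               "at least one")
})

test_that("every optimizer can take a descent step", {
  d <- synthetic_xy(40, seed = 10L)
  for (opt in c("sgd", "adagrad", "adadelta", "rmsprop", "adam", "adamax",
                "nadam")) {
    m <- scar_surrogate(d$X, d$Y, optimizer = opt, lr = 0.01,
                        max_epochs = 8L, seed = 2L)
    h <- m$history
    expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  }
})
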