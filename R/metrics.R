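# Multi-target regression performance measures and the evaluation report.

#' Coefficient of determination
#'
#' `R^2 = 1 - sum(e^2) / sum((y - mean(y))^2)` pooled over all supplied
#' values; can be negative when the predictions do worse than the target
#' mean.
#'
#' @param targets Numeric vector or matrix of reference values.
#' @param predictions Matching predictions.
#' @return Scalar R squared.
#' @export
r_squared <- function(targets, predictions) {
  y <- as.numeric(targets)
  yh <- as.numeric(predictions)
  if (length(y) != length(yh)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2) stop("need at least two values", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    stop("targets are constant: R^2 denominator is zero", call. = FALSE)
  }
  1 - sum((y - yh)^2) / ss_tot
}

#' Average relative root-mean-squared error
#'
#' For an n x d target matrix, the RRMSE of each target dimension is its
#' root summed squared error normalised by the root summed squared deviation
#' of the targets from their mean; the aRRMSE is the mean over the d
#' dimensions. Values below 0.1 are conventionally read as excellent
#' multi-target regression.
#'
#' @param targets n x d matrix of reference values.
#' @param predictions Matching prediction matrix.
#' @return Scalar aRRMSE (nonnegative).
#' @export
arrmse <- function(targets, predictions) {
  Y <- as.matrix(targets)
  Yh <- as.matrix(predictions)
  if (!all(dim(Y) == dim(Yh))) stop("shape mismatch", call. = FALSE)
  ss_tot <- colSums(sweep(Y, 2, colMeans(Y))^2)
  bad <- which(ss_tot <= 0)
  if (length(bad)) {
    stop(sprintf("target column %d is constant: RRMSE undefined", bad[1]),
         call. = FALSE)
  }
  mean(sqrt(colSums((Y - Yh)^2) / ss_tot))
}

#' Average relative error
#'
#' Mean over all entries of `|e| / |y|`; requires nonzero targets (RSA
#' values are strictly positive).
#'
#' @inheritParams r_squared
#' @return Scalar mean relative error.
#' @export
arelerr <- function(targets, predictions) {
  y <- as.numeric(targets)
  yh <- as.numeric(predictions)
  if (length(y) != length(yh)) stop("length mismatch", call. = FALSE)
  if (any(y == 0)) stop("zero target: relative error undefined", call. = FALSE)
  mean(abs(y - yh) / abs(y))
}

#' Mean absolute error
#'
#' @inheritParams r_squared
#' @return Scalar MAE.
#' @export
mae <- function(targets, predictions) {
  mean(abs(as.numeric(targets) - as.numeric(predictions)))
}

#' Minimum and last RSA of a course
#'
#' The minimum RSA marks maximal contraction during healing; the last value
#' is the (near-)asymptotic permanent contraction after remodelling.
#'
#' @param rsa A single RSA course (vector) or a matrix of courses (one per
#'   row).
#' @return For a vector, `c(min =, last =)`; for a matrix, an n x 2 matrix
#'   with columns `min` and `last`.
#' @export
min_last_rsa <- function(rsa) {
  if (is.matrix(rsa)) {
    if (ncol(rsa) < 1) stop("empty RSA course", call. = FALSE)
    return(cbind(min = apply(rsa, 1, min), last = rsa[, ncol(rsa)]))
  }
  if (length(rsa) < 1) stop("empty RSA course", call. = FALSE)
  c(min = min(rsa), last = rsa[length(rsa)])
}

characteristic_block <- function(y, yh) {
  list(r2 = r_squared(y, yh), mae = mae(y, yh), min = min(y), max = max(y),
       range = max(y) - min(y), average = mean(y))
}

#' Cross-validate the surrogate over the training folds
#'
#' Trains one surrogate per fold (fold rows held out and monitored for early
#' stopping) and scores it on the held-out fold.
#'
#' @param split A `scar_split`.
#' @param ... Training settings passed to [scar_surrogate()].
#' @param keep_models Keep the fitted fold models (default drops them).
#' @param verbose Print one line per fold.
#' @return List with `scores` (data.frame: fold, r2, arrmse, arelerr) and
#'   optionally `models`.
#' @export
cross_validate <- function(split, ..., keep_models = FALSE,
                           verbose = FALSE) {
  scores <- list()
  models <- list()
  for (k in seq_along(split$folds)) {
    hold <- split$folds[[k]]
    m <- scar_surrogate(split$Xs_train[-hold, , drop = FALSE],
                        split$Y_train[-hold, , drop = FALSE],
                        validation = list(
                          x = split$Xs_train[hold, , drop = FALSE],
                          y = split$Y_train[hold, , drop = FALSE]),
                        scaler = split$scaler, ...)
    yh <- predict(m, split$Xs_train[hold, , drop = FALSE], scaled = TRUE)
    yk <- split$Y_train[hold, , drop = FALSE]
    scores[[k]] <- data.frame(fold = k, r2 = r_squared(yk, yh),
                              arrmse = arrmse(yk, yh),
                              arelerr = arelerr(yk, yh))
    if (keep_models) models[[k]] <- m
    if (verbose) {
      message(sprintf("fold %2d: R^2 %.4f aRRMSE %.4f aRelErr %.5f",
                      k, scores[[k]]$r2, scores[[k]]$arrmse,
                      scores[[k]]$arelerr))
    }
  }
  out <- list(scores = do.call(rbind, scores))
  if (keep_models) out$models <- models
  out
}

#' Evaluate a surrogate on the held-out test set
#'
#' Builds the full performance report: pooled test metrics (R^2, aRRMSE,
#' aRelErr), cross-validation mean and sample standard deviation per metric
#' when fold scores are supplied, and per-characteristic blocks (minimum and
#' last RSA: R^2, MAE and the distribution of the characteristic over the
#' test set).
#'
#' @param model A fitted `scar_surrogate`.
#' @param split A `scar_split` providing the held-out test rows.
#' @param cv Optional result of [cross_validate()].
#' @return Object of class `scar_report`.
#' @export
evaluate_surrogate <- function(model, split, cv = NULL) {
  yh <- predict(model, split$Xs_test, scaled = TRUE)
  y <- split$Y_test
  ml_y <- min_last_rsa(y)
  ml_yh <- min_last_rsa(yh)
  rep <- list(
    test = list(r2 = r_squared(y, yh), arrmse = arrmse(y, yh),
                arelerr = arelerr(y, yh)),
    min_rsa = characteristic_block(ml_y[, "min"], ml_yh[, "min"]),
    last_rsa = characteristic_block(ml_y[, "last"], ml_yh[, "last"]),
    n_test = nrow(y))
  if (!is.null(cv)) {
    s <- cv$scores
    rep$cv <- list(
      r2 = c(mean = mean(s$r2), sd = sd(s$r2)),
      arrmse = c(mean = mean(s$arrmse), sd = sd(s$arrmse)),
      arelerr = c(mean = mean(s$arelerr), sd = sd(s$arelerr)),
      n_folds = nrow(s))
  }
  structure(rep, class = "scar_report")
}

#' @export
print.scar_report <- function(x, ...) {
  cat("Surrogate performance\n")
  cat(sprintf("%-12s %-22s %s\n", "measure", "cross-validation", "test"))
  fmt_cv <- function(m) {
    if (is.null(x$cv)) "-" else sprintf("%.4f +/- %.4f", x$cv[[m]]["mean"],
                                        x$cv[[m]]["sd"])
  }
  cat(sprintf("%-12s %-22s %.4f\n", "R^2", fmt_cv("r2"), x$test$r2))
  cat(sprintf("%-12s %-22s %.4f\n", "aRRMSE", fmt_cv("arrmse"),
              x$test$arrmse))
  cat(sprintf("%-12s %-22s %.4f\n", "aRelErr", fmt_cv("arelerr"),
              x$test$arelerr))
  cat(sprintf("\nCharacteristics over the %d test courses\n", x$n_test))
  cat(sprintf("%-12s %8s %8s %8s %8s %8s %8s\n", "", "R^2", "MAE", "min",
              "max", "range", "average"))
  for (nm in c("min_rsa", "last_rsa")) {
    b <- x[[nm]]
    cat(sprintf("%-12s %8.4f %8.4f %8.4f %8.4f %8.4f %8.4f\n",
                sub("_rsa", " RSA", nm), b$r2, b$mae, b$min, b$max, b$range,
                b$average))
  }
  invisible(x)
}

#' Serialise a performance report to JSON
#'
#' @param report A `scar_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
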