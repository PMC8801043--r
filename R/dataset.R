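# Corpus generation: stability-constrained uniform parameter sampling,
# solver runs, train/test splitting and Min-Max scaling.

# deterministic per-row seed derived from (master_seed, index); keeps every
# row individually reproducible regardless of corpus size
row_seed <- function(master_seed, index, attempt = 0L) {
  as.integer((as.numeric(master_seed) * 48271 + index * 16807 +
                attempt * 69621) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw one admissible parameter set
#'
#' Uniform draw of the 25 varied parameters from their configured ranges,
#' rejection-resampled until the stability condition
#' `k_c < delta_c rho_bar a_c_II` holds (the full vector is re-drawn on
#' rejection).
#'
#' @param ranges A `scar_ranges` configuration.
#' @param seed Integer seed; the accepted draw is reproducible from it.
#' @param max_rejections Abort with a configuration error after this many
#'   consecutive rejections (acceptance probability effectively zero).
#' @return A `scar_params` with attributes `seed` and `rejections`.
#' @export
sample_params <- function(ranges = scar_ranges(), seed,
                          max_rejections = 1e5) {
  vn <- varied_names(ranges)
  lo <- vapply(ranges[vn], `[[`, 0.0, "min")
  hi <- vapply(ranges[vn], `[[`, 0.0, "max")
  with_seed(seed, {
    rejections <- 0L
    repeat {
      vals <- stats::runif(length(vn), lo, hi)
      names(vals) <- vn
      p <- tryCatch(do.call(scar_params, c(as.list(vals),
                                           list(ranges = ranges))),
                    error = function(e) NULL)
      if (!is.null(p) && check_stability(p)) {
        attr(p, "seed") <- seed
        attr(p, "rejections") <- rejections
        return(p)
      }
      rejections <- rejections + 1L
      if (rejections >= max_rejections) {
        stop("no admissible parameter sample found: the configured ranges ",
             "are incompatible with the stability condition", call. = FALSE)
      }
    }
  })
}

#' Generate a simulation corpus
#'
#' Draws `n` stability-admissible parameter sets, runs the finite-element
#' model for each, and collects the inputs (n x 25) and the daily RSA
#' courses (n x 365). Rows are individually reproducible from
#' `(master_seed, row index)`; solver failures are logged and the row is
#' resampled with a fresh derived seed. The run aborts if more than 5% of
#' attempted simulations fail.
#'
#' @param n Number of corpus rows.
#' @param ranges A `scar_ranges` configuration.
#' @param mesh A `scar_mesh` used for every simulation.
#' @param control A `scar_control` used for every simulation.
#' @param master_seed Integer master seed.
#' @param verbose Print progress every 100 rows.
#' @return Object of class `scar_corpus`: list with `X` (n x 25 raw varied
#'   inputs), `Y` (n x days RSA targets), `seeds`, `failures` (log of
#'   resampled rows) and provenance (`ranges`, mesh size, control).
#' @export
generate_corpus <- function(n, ranges = scar_ranges(),
                            mesh = NULL, control = scar_control(),
                            master_seed = 1L, verbose = FALSE) {
  stopifnot(n >= 1)
  vn <- varied_names(ranges)
  X <- matrix(NA_real_, n, length(vn), dimnames = list(NULL, vn))
  Y <- matrix(NA_real_, n, control$days)
  seeds <- integer(n)
  failures <- list()
  attempts <- 0L
  for (i in seq_len(n)) {
    attempt <- 0L
    repeat {
      sd_i <- row_seed(master_seed, i, attempt)
      p <- sample_params(ranges, seed = sd_i)
      msh <- if (is.null(mesh)) scar_mesh(p) else mesh
      attempts <- attempts + 1L
      sim <- tryCatch(scar_simulate(p, mesh = msh, control = control),
                      error = function(e) e)
      if (!inherits(sim, "error")) {
        X[i, ] <- vapply(vn, function(nm) p[[nm]], 0.0)
        Y[i, ] <- sim$rsa
        seeds[i] <- sd_i
        break
      }
      failures[[length(failures) + 1L]] <-
        list(row = i, seed = sd_i, message = conditionMessage(sim))
      attempt <- attempt + 1L
      if (attempts >= 100L && length(failures) > 0.05 * attempts) {
        stop(sprintf(paste0("solver failure rate exceeded 5%% ",
                            "(%d failures in %d attempts); last error: %s"),
             length(failures), attempts, conditionMessage(sim)),
             call. = FALSE)
      }
    }
    if (verbose && i %% 100 == 0) {
      message(sprintf("corpus: %d/%d rows", i, n))
    }
  }
  structure(list(X = X, Y = Y, seeds = seeds, failures = failures,
                 ranges = ranges, n_nodes = if (is.null(mesh)) 202L
                   else length(mesh$x),
                 control = control, master_seed = master_seed),
            class = "scar_corpus")
}

#' @export
print.scar_corpus <- function(x, ...) {
  cat(sprintf("scar_corpus: %d simulations, %d inputs -> %d daily RSA values\n",
              nrow(x$X), ncol(x$X), ncol(x$Y)))
  cat(sprintf("  min RSA in [%.3f, %.3f]; last RSA in [%.3f, %.3f]\n",
              min(apply(x$Y, 1, min)), max(apply(x$Y, 1, min)),
              min(x$Y[, ncol(x$Y)]), max(x$Y[, ncol(x$Y)])))
  cat(sprintf("  %d solver failures resampled\n", length(x$failures)))
  invisible(x)
}

#' Min-Max feature scaler
#'
#' Fits per-feature minimum and maximum (on training inputs only) and maps
#' features affinely into `[0, 1]`.
#'
#' @param x Numeric matrix of raw inputs (rows = samples).
#' @return Object of class `scar_scaler` with fields `min` and `max`.
#' @export
fit_scaler <- function(x) {
  mn <- apply(x, 2, min)
  mx <- apply(x, 2, max)
  if (any(mx <= mn)) {
    stop("scaler needs max > min for every feature", call. = FALSE)
  }
  structure(list(min = mn, max = mx), class = "scar_scaler")
}

#' Apply a fitted Min-Max scaler
#'
#' @param scaler A `scar_scaler`.
#' @param x Raw input matrix (columns in fitting order).
#' @param warn Warn (once per call) when inputs fall outside the fitted
#'   range.
#' @return Matrix of scaled inputs.
#' @export
scale_features <- function(scaler, x, warn = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$min)) {
    stop(sprintf("input has %d columns, scaler was fitted on %d features",
                 ncol(x), length(scaler$min)), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, scaler$min, "-"), 2, scaler$max - scaler$min, "/")
  if (warn && (any(z < -1e-9) || any(z > 1 + 1e-9))) {
    warning("inputs outside the scaler's fitted range; predictions are extrapolations",
            call. = FALSE)
  }
  z
}

#' Split a corpus and fit the input scaler
#'
#' Holds out a test fraction, partitions the training portion into
#' cross-validation folds, and fits the Min-Max input scaler on the training
#' rows only (no leakage from the test set).
#'
#' @param corpus A `scar_corpus` (or a list with matrices `X` and `Y`).
#' @param train_fraction Fraction of rows used for training (default 0.8).
#' @param n_folds Number of cross-validation folds over the training rows
#'   (default 10).
#' @param seed Integer seed for the shuffling.
#' @return Object of class `scar_split`: raw and scaled train/test arrays,
#'   fold index list (into the training arrays), the fitted `scaler` and the
#'   original row indices.
#' @export
split_and_scale <- function(corpus, train_fraction = 0.8, n_folds = 10L,
                            seed = 1L) {
  X <- corpus$X
  Y <- corpus$Y
  n <- nrow(X)
  n_train <- round(train_fraction * n)
  if (n_train < n_folds || n_train < 1 || n_train >= n) {
    stop("not enough rows for the requested split/folds", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  idx_train <- sort(perm[seq_len(n_train)])
  idx_test <- sort(perm[(n_train + 1):n])
  folds <- with_seed(seed + 1L, {
    shuffled <- sample(seq_len(n_train))
    split(shuffled, rep_len(seq_len(n_folds), n_train))
  })
  folds <- lapply(folds, sort)
  if (any(lengths(folds) < 1L)) stop("empty cross-validation fold")
  scaler <- fit_scaler(X[idx_train, , drop = FALSE])
  structure(list(
    X_train = X[idx_train, , drop = FALSE],
    Y_train = Y[idx_train, , drop = FALSE],
    X_test = X[idx_test, , drop = FALSE],
    Y_test = Y[idx_test, , drop = FALSE],
    Xs_train = scale_features(scaler, X[idx_train, , drop = FALSE]),
    Xs_test = scale_features(scaler, X[idx_test, , drop = FALSE],
                             warn = FALSE),
    folds = folds, scaler = scaler,
    idx_train = idx_train, idx_test = idx_test, seed = seed),
    class = "scar_split")
}

#' @export
print.scar_split <- function(x, ...) {
  cat(sprintf("scar_split: %d train / %d test rows, %d folds\n",
              nrow(x$X_train), nrow(x$X_test), length(x$folds)))
  invisible(x)
}

#' Write a corpus to a directory container
#'
#' Plain-text container: `X.csv`, `Y.csv`, `seeds.csv` plus a `meta.json`
#' sidecar with the ranges, solver settings and master seed.
#'
#' @param corpus A `scar_corpus`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(as.data.frame(corpus$X), file.path(dir, "X.csv"))
  data.table::fwrite(as.data.frame(corpus$Y), file.path(dir, "Y.csv"))
  data.table::fwrite(data.frame(seed = corpus$seeds),
                     file.path(dir, "seeds.csv"))
  meta <- list(n = nrow(corpus$X), days = ncol(corpus$Y),
               n_nodes = corpus$n_nodes, master_seed = corpus$master_seed,
               control = unclass(corpus$control),
               ranges = lapply(corpus$ranges, unclass),
               n_failures = length(corpus$failures))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a corpus directory container
#'
#' @param dir Directory written by [write_corpus()].
#' @return A `scar_corpus`.
#' @export
read_corpus <- function(dir) {
  X <- as.matrix(data.table::fread(file.path(dir, "X.csv")))
  Y <- as.matrix(data.table::fread(file.path(dir, "Y.csv")))
  seeds <- data.table::fread(file.path(dir, "seeds.csv"))$seed
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ranges <- structure(lapply(meta$ranges, as.list), class = "scar_ranges")
  structure(list(X = X, Y = unname(Y), seeds = seeds, failures = list(),
                 ranges = ranges, n_nodes = meta$n_nodes,
                 control = do.call(scar_control,
                                   meta$control[c("dt", "days", "picard_tol",
                                                  "picard_max", "boundary",
                                                  "snapshot_every")]),
                 master_seed = meta$master_seed),
            class = "scar_corpus")
}
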