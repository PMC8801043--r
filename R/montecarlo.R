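# Monte-Carlo uncertainty propagation through the trained surrogate: the
# engine behind patient-specific contraction prognosis.

#' Define a patient scenario for Monte-Carlo propagation
#'
#' Each of the 25 surrogate inputs gets either a point value or a uniform
#' distribution `list(min =, max =)`; parameters not mentioned default to
#' their configured point value. Draws violating the stability condition
#' are rejected and redrawn, mirroring the corpus sampler.
#'
#' @param ... Named distribution specs: a single number (point mass) or
#'   `c(min, max)` / `list(min =, max =)` for a uniform distribution.
#' @param draws Number of Monte-Carlo draws (default 5000).
#' @param seed Integer seed.
#' @param quantiles Quantile levels of the per-day RSA bands.
#' @param contraction_threshold Report the probability that peak contraction
#'   `1 - min(RSA)` exceeds this fraction (default 0.25).
#' @param ranges Parameter configuration supplying defaults and the
#'   stability context.
#' @return Object of class `scar_scenario`.
#' @export
scar_scenario <- function(..., draws = 5000L, seed = 1L,
                          quantiles = c(0.05, 0.25, 0.5, 0.75, 0.95),
                          contraction_threshold = 0.25,
                          ranges = scar_ranges()) {
  spec <- list(...)
  if (length(spec) == 1L && is.null(names(spec)) && is.list(spec[[1]])) {
    spec <- spec[[1]]
  }
  vn <- varied_names(ranges)
  unknown <- setdiff(names(spec), vn)
  if (length(unknown)) {
    stop("unknown scenario parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dists <- lapply(vn, function(nm) {
    d <- spec[[nm]]
    if (is.null(d)) return(list(type = "point", value = ranges[[nm]]$value))
    if (is.list(d)) d <- c(d$min, d$max)
    d <- as.numeric(d)
    if (length(d) == 1) return(list(type = "point", value = d))
    if (length(d) == 2 && d[1] <= d[2]) {
      return(list(type = "uniform", min = d[1], max = d[2]))
    }
    stop(sprintf("invalid distribution for %s", nm), call. = FALSE)
  })
  names(dists) <- vn
  if (draws < 1) stop("draws must be at least 1", call. = FALSE)
  structure(list(dists = dists, draws = as.integer(draws),
                 seed = as.integer(seed), quantiles = sort(quantiles),
                 contraction_threshold = contraction_threshold,
                 ranges = ranges),
            class = "scar_scenario")
}

#' @export
print.scar_scenario <- function(x, ...) {
  nv <- sum(vapply(x$dists, function(d) d$type != "point", TRUE))
  cat(sprintf("scar_scenario: %d draws, %d uncertain of %d parameters, seed %d\n",
              x$draws, nv, length(x$dists), x$seed))
  for (nm in names(x$dists)) {
    d <- x$dists[[nm]]
    if (d$type != "point") {
      cat(sprintf("  %-12s U[%.4g, %.4g]\n", nm, d$min, d$max))
    }
  }
  invisible(x)
}

# vectorised stability-filtered draws of the scenario; returns draws x 25
scenario_draws <- function(scenario, n) {
  vn <- names(scenario$dists)
  fixed <- scenario$ranges
  out <- matrix(NA_real_, 0, length(vn), dimnames = list(NULL, vn))
  tries <- 0L
  while (nrow(out) < n) {
    m <- max(n - nrow(out), 1L)
    block <- vapply(scenario$dists, function(d) {
      if (d$type == "point") rep(d$value, m)
      else stats::runif(m, d$min, d$max)
    }, numeric(m))
    if (m == 1L) block <- matrix(block, nrow = 1,
                                 dimnames = list(NULL, vn))
    thr <- block[, "delta_c"] * block[, "rho_bar"] * block[, "a_c_II"]
    ok <- block[, "k_c"] < thr
    out <- rbind(out, block[ok, , drop = FALSE])
    tries <- tries + 1L
    if (tries > 1000L && nrow(out) == 0L) {
      stop("all Monte-Carlo draws rejected by the stability condition",
           call. = FALSE)
    }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Monte-Carlo uncertainty propagation through the surrogate
#'
#' Samples the scenario's parameter distributions (stability-filtered),
#' predicts all RSA courses in one batch, and summarises the induced
#' distribution: per-day quantile bands, distributions of the minimum and
#' last RSA, and the probability that peak contraction exceeds the
#' scenario's threshold. Per-draw predictions are retained (up to `keep`)
#' so every summary can be recounted.
#'
#' @param model A fitted `scar_surrogate`.
#' @param scenario A `scar_scenario`.
#' @param keep Maximum number of draw-level predictions stored in the
#'   result (default 10000).
#' @return Object of class `scar_mc`: `quantile_curves` (days x quantiles),
#'   `min_rsa`, `last_rsa` (per-draw vectors), `p_exceed`, `draws` (inputs),
#'   `predictions` (up to `keep` rows), `scenario`.
#' @export
run_monte_carlo <- function(model, scenario, keep = 10000L) {
  X <- with_seed(scenario$seed, scenario_draws(scenario, scenario$draws))
  extrapolated <- FALSE
  Yh <- withCallingHandlers(
    predict(model, X),
    warning = function(w) {
      if (grepl("fitted range", conditionMessage(w))) {
        extrapolated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  qc <- t(apply(Yh, 2, stats::quantile, probs = scenario$quantiles))
  colnames(qc) <- sprintf("q%02.0f", 100 * scenario$quantiles)
  ml <- min_last_rsa(Yh)
  p_exceed <- mean(1 - ml[, "min"] > scenario$contraction_threshold)
  nk <- min(nrow(Yh), keep)
  structure(list(quantile_curves = qc,
                 min_rsa = ml[, "min"], last_rsa = ml[, "last"],
                 p_exceed = p_exceed, extrapolated = extrapolated,
                 draws = X[seq_len(nk), , drop = FALSE],
                 predictions = Yh[seq_len(nk), , drop = FALSE],
                 scenario = scenario),
            class = "scar_mc")
}

#' @export
print.scar_mc <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary over %d draws\n", length(x$min_rsa)))
  cat(sprintf("  min RSA: median %.3f [%.3f, %.3f] (5-95%%)\n",
              stats::median(x$min_rsa),
              stats::quantile(x$min_rsa, 0.05),
              stats::quantile(x$min_rsa, 0.95)))
  cat(sprintf("  last RSA: median %.3f [%.3f, %.3f] (5-95%%)\n",
              stats::median(x$last_rsa),
              stats::quantile(x$last_rsa, 0.05),
              stats::quantile(x$last_rsa, 0.95)))
  cat(sprintf("  P(peak contraction > %.0f%%) = %.3f\n",
              100 * x$scenario$contraction_threshold, x$p_exceed))
  if (isTRUE(x$extrapolated)) {
    cat("  note: some draws lie outside the surrogate's fitted input range\n")
  }
  invisible(x)
}

#' @export
plot.scar_mc <- function(x, ...) {
  qc <- x$quantile_curves
  days <- seq_len(nrow(qc))
  graphics::plot(NA, xlim = range(days), ylim = c(0, 1), xlab = "day",
                 ylab = "relative surface area", ...)
  for (j in seq_len(ncol(qc))) {
    graphics::lines(days, qc[, j], lty = if (j == (ncol(qc) + 1) %/% 2) 1
                    else 2)
  }
  invisible(x)
}

#' Write Monte-Carlo outputs to a directory
#'
#' `quantiles.csv` holds the per-day quantile curves (one row per day),
#' `summary.json` the scalar summaries; optionally a PNG of the quantile
#' bands.
#'
#' @param mc A `scar_mc`.
#' @param dir Output directory (created if missing).
#' @param plot Also write `bands.png`.
#' @return `dir`, invisibly.
#' @export
write_mc_report <- function(mc, dir, plot = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qc <- as.data.frame(mc$quantile_curves)
  qc <- cbind(day = seq_len(nrow(qc)), qc)
  data.table::fwrite(qc, file.path(dir, "quantiles.csv"))
  sm <- list(draws = length(mc$min_rsa),
             seed = mc$scenario$seed,
             contraction_threshold = mc$scenario$contraction_threshold,
             p_exceed = mc$p_exceed,
             min_rsa = list(mean = mean(mc$min_rsa), sd = sd(mc$min_rsa),
                            median = stats::median(mc$min_rsa)),
             last_rsa = list(mean = mean(mc$last_rsa), sd = sd(mc$last_rsa),
                             median = stats::median(mc$last_rsa)))
  jsonlite::write_json(sm, file.path(dir, "summary.json"), digits = NA,
                       auto_unbox = TRUE)
  if (plot) {
    grDevices::png(file.path(dir, "bands.png"), width = 800, height = 500)
    plot(mc)
    grDevices::dev.off()
  }
  invisible(dir)
}
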