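# Parameter sets for the 1D morphoelastic contraction model.
#
# The 25 entries flagged `varied` in the shipped configuration form the
# surrogate input vector; the remaining entries are fixed model constants.
# Two quantities are derived rather than free:
#   kappa_F   = (1 - delta_N / r_F) / N_bar   (logistic crowding, fixes N_bar
#               as the fibroblast equilibrium)
#   delta_rho = k_rho / rho_bar               (fixes rho_bar as the collagen
#               equilibrium)

# parameters that may legitimately be switched off (rate-like); all others
# must be strictly positive
.zero_ok <- c("chi_F", "r_F", "r_F_max", "k_F", "delta_N", "delta_M",
              "k_c", "delta_c", "eta_I", "eta_II", "k_rho", "k_rho_max",
              "xi", "zeta", "D_F", "wound_N_frac", "wound_rho_frac", "E_mod")

#' Default parameter configuration
#'
#' Reads the packaged parameter configuration (defaults, units and the
#' uniform sampling ranges of the 25 varied parameters).
#'
#' @param file Optional path to a YAML/JSON configuration with one key per
#'   parameter, each holding `value` and, for varied parameters,
#'   `min`/`max`/`varied: true`. Defaults to the configuration shipped with
#'   the package.
#' @return An object of class `scar_ranges`: a named list of per-parameter
#'   specs.
#' @export
scar_ranges <- function(file = NULL) {
  if (is.null(file)) {
    if (!is.null(.morphoscar_env$default_ranges)) {
      return(.morphoscar_env$default_ranges)
    }
    file <- system.file("extdata", "param_ranges.yaml", package = "morphoscar",
                        mustWork = TRUE)
  }
  raw <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  spec <- lapply(raw, function(p) {
    p$varied <- isTRUE(p$varied)
    if (p$varied) {
      if (is.null(p$min) || is.null(p$max)) {
        stop("varied parameters need both `min` and `max`", call. = FALSE)
      }
      if (p$min > p$max) stop("range with min > max", call. = FALSE)
    }
    p
  })
  out <- structure(spec, class = "scar_ranges")
  n_var <- sum(vapply(spec, `[[`, TRUE, "varied"))
  if (n_var != 25L) {
    warning(sprintf("configuration flags %d varied parameters (surrogate expects 25)",
                    n_var))
  }
  if (is.null(.morphoscar_env$default_ranges) &&
      identical(file, system.file("extdata", "param_ranges.yaml",
                                  package = "morphoscar"))) {
    .morphoscar_env$default_ranges <- out
  }
  out
}

#' @export
print.scar_ranges <- function(x, ...) {
  varied <- names(x)[vapply(x, `[[`, TRUE, "varied")]
  cat("Parameter configuration:", length(x), "parameters,",
      length(varied), "varied\n")
  for (nm in names(x)) {
    p <- x[[nm]]
    if (p$varied) {
      cat(sprintf("  %-14s %-10.4g U[%.4g, %.4g]  %s\n", nm, p$value,
                  p$min, p$max, p$unit %||% ""))
    } else {
      cat(sprintf("  %-14s %-10.4g fixed           %s\n", nm, p$value,
                  p$unit %||% ""))
    }
  }
  invisible(x)
}

#' Names of the varied (surrogate input) parameters
#'
#' @param ranges A `scar_ranges` object.
#' @return Character vector of the parameter names forming the surrogate
#'   input vector, in configuration order.
#' @export
varied_names <- function(ranges = scar_ranges()) {
  names(ranges)[vapply(ranges, `[[`, TRUE, "varied")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a model parameter set
#'
#' Builds a validated parameter set for the morphoelastic contraction model.
#' Values not supplied default to the packaged configuration. Derived
#' quantities (`kappa_F`, `delta_rho`) are computed so that
#' (c = 0, M = 0, N = N_bar, rho = rho_bar, v = 0, eps = 0) is an exact
#' homeostatic equilibrium.
#'
#' @param ... Named parameter values overriding the defaults (see
#'   [scar_ranges()] for names and units).
#' @param ranges Parameter configuration supplying defaults.
#' @return Object of class `scar_params`; a named list of numeric values with
#'   derived entries, supporting `$is_stable`.
#' @export
scar_params <- function(..., ranges = scar_ranges()) {
  defaults <- lapply(ranges, `[[`, "value")
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- modifyList(defaults, over)
  p <- lapply(p, as.numeric)
  validate_params(p)
  # derived quantities
  p$kappa_F <- if (p$r_F > 0) (1 - p$delta_N / p$r_F) / p$N_bar else 0
  p$delta_rho <- p$k_rho / p$rho_bar
  structure(p, class = "scar_params")
}

validate_params <- function(p) {
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("non-finite parameter value", call. = FALSE)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (nm %in% .zero_ok) {
      if (v < 0) stop(sprintf("parameter %s must be nonnegative", nm),
                      call. = FALSE)
    } else if (v <= 0) {
      stop(sprintf("parameter %s must be strictly positive", nm),
           call. = FALSE)
    }
  }
  if (p$L >= p$domain_length) {
    stop("wound length L must be smaller than the domain length",
         call. = FALSE)
  }
  if (p$r_F > 0 && p$delta_N >= p$r_F) {
    stop("fibroblast apoptosis must be slower than proliferation (delta_N < r_F)",
         call. = FALSE)
  }
  if (p$wound_N_frac > 1 || p$wound_rho_frac > 1) {
    stop("wound density fractions must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Linear-stability admissibility of a parameter set
#'
#' The homeostatic equilibrium of the signalling equation is linearly stable
#' iff the secretion rate is dominated by decay:
#' `k_c < delta_c * rho_bar * a_c_II` (strict). Parameter sets violating this
#' produce self-amplifying signalling and are rejected by the corpus sampler.
#'
#' @param params A `scar_params` object, or a named list/vector providing
#'   `k_c`, `delta_c`, `rho_bar` and `a_c_II`.
#' @return `TRUE` iff the strict inequality holds.
#' @export
check_stability <- function(params) {
  need <- c("k_c", "delta_c", "rho_bar", "a_c_II")
  v <- vapply(need, function(nm) as.numeric(params[[nm]]), 0.0)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("check_stability needs strictly positive k_c, delta_c, rho_bar and a_c_II",
         call. = FALSE)
  }
  unname(v["k_c"] < v["delta_c"] * v["rho_bar"] * v["a_c_II"])
}

#' @export
`$.scar_params` <- function(x, name) {
  if (identical(name, "is_stable")) return(check_stability(x))
  NextMethod()
}

#' @export
print.scar_params <- function(x, ...) {
  cat("Morphoelastic model parameter set\n")
  cat(sprintf("  wound half-length L = %.3g cm on a %.3g cm half domain\n",
              x$L, x$domain_length))
  cat(sprintf("  equilibrium: N_bar = %.3g cells/cm^3, rho_bar = %.3g g/cm^3\n",
              x$N_bar, x$rho_bar))
  cat(sprintf("  stability (k_c < delta_c rho_bar a_c_II): %s  [%.3g < %.3g]\n",
              if (x$is_stable) "stable" else "UNSTABLE",
              x$k_c, x$delta_c * x$rho_bar * x$a_c_II))
  invisible(x)
}

# canonical parameter order used by the compiled solver
.param_order <- c("L", "steepness", "D_c", "D_F", "chi_F", "r_F", "r_F_max",
                  "k_F", "delta_N", "delta_M", "k_c", "a_c_I", "a_c_II",
                  "delta_c", "eta_I", "eta_II", "k_rho", "k_rho_max",
                  "rho_bar", "N_bar", "mu", "E_mod", "xi", "R_sat", "zeta",
                  "domain_length", "rho_t", "a_c_III", "a_c_IV", "c_w",
                  "wound_N_frac", "wound_rho_frac", "kappa_F", "delta_rho")

as_param_vector <- function(params) {
  stopifnot(inherits(params, "scar_params"))
  vapply(.param_order, function(nm) params[[nm]], 0.0)
}

#' Homeostatic equilibrium state
#'
#' Nodal state at the healthy (unwounded) fixed point: no signalling, no
#' myofibroblasts, fibroblasts and collagen at their equilibrium densities,
#' zero velocity and zero effective strain.
#'
#' @param params A `scar_params` object.
#' @param mesh A `scar_mesh` object (see [scar_mesh()]).
#' @return A `scar_state` object (matrix of nodal values, columns
#'   `c`, `N`, `M`, `rho`, `v`, `eps`, attribute `time`).
#' @export
equilibrium_state <- function(params, mesh = scar_mesh(params)) {
  n <- length(mesh$x)
  scar_state(c = rep(0, n), N = rep(params$N_bar, n), M = rep(0, n),
             rho = rep(params$rho_bar, n), v = rep(0, n), eps = rep(0, n),
             time = 0)
}
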