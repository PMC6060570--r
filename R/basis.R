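#' Gaussian kernel basis configuration
#'
#' The trajectory basis is a constant plus `p - 1` Gaussian bumps:
#' `b_1(t) = 1` and `b_m(t) = exp(-b (t - phi_m)^2)` for `m = 2..p`, with
#' kernel centers `phi_m` (days) and bandwidth `b` (days^-2). Time is
#' scalar here, so the isotropic kernel reduces to a 1-D squared distance.
#'
#' @param p Number of basis functions (constant included), `p >= 2`.
#' @param locations Strictly increasing kernel centers, length `p - 1`.
#' @param bandwidth Positive kernel bandwidth in days^-2.
#' @return An object of class `basis_config`.
#' @seealso [default_basis()]
#' @export
basis_config <- function(p, locations, bandwidth) {
  if (p < 2) abort("p must be >= 2", class = "pp_config_error")
  if (length(locations) != p - 1) {
    abort("locations must have length p - 1", class = "pp_config_error")
  }
  if (is.unsorted(locations, strictly = TRUE)) {
    abort("locations must be strictly increasing", class = "pp_config_error")
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    abort("bandwidth must be positive", class = "pp_config_error")
  }
  structure(list(p = as.integer(p), locations = as.numeric(locations),
                 bandwidth = as.numeric(bandwidth)),
            class = "basis_config")
}

#' @export
print.basis_config <- function(x, ...) {
  cat("Gaussian kernel basis: p =", x$p,
      "(constant + ", x$p - 1, "kernels),",
      "bandwidth =", signif(x$bandwidth, 4), "days^-2\n")
  cat("centers:", paste(signif(x$locations, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Default basis over a season
#'
#' Places `p - 1` kernel centers equally spaced over `[0, t_max]` and sets
#' the bandwidth by the half-overlap rule: adjacent kernels intersect at
#' height 1/2, i.e. `b = log(2) / (spacing / 2)^2`. With `p = 2` the
#' single kernel sits at `t_max / 2` with the spacing taken as `t_max`.
#'
#' @param t_max Season length in days (`> 0`).
#' @param p Number of basis functions, default 20 (about 19-day kernel
#'   spacing over a 360-day season; shrinkage in the factor model prunes
#'   excess elements).
#' @return A [basis_config()].
#' @export
default_basis <- function(t_max, p = 20) {
  if (t_max <= 0) abort("t_max must be positive", class = "pp_config_error")
  if (p < 2) abort("p must be >= 2", class = "pp_config_error")
  if (p == 2) {
    spacing <- t_max
    locations <- t_max / 2
  } else {
    locations <- seq(0, t_max, length.out = p - 1)
    spacing <- locations[2] - locations[1]
  }
  basis_config(p, locations, log(2) / (spacing / 2)^2)
}

#' Evaluate the basis at one time point
#'
#' @param t A single finite time (days).
#' @param cfg A [basis_config()].
#' @return Numeric vector of length `p`; first component is exactly 1.
#' @export
evaluate_basis <- function(t, cfg) {
  stopifnot(inherits(cfg, "basis_config"))
  if (length(t) != 1 || !is.finite(t)) {
    abort("t must be a single finite number", class = "pp_domain_error")
  }
  c(1, exp(-cfg$bandwidth * (t - cfg$locations)^2))
}

#' Basis design matrix
#'
#' Row `j` is the basis evaluated at `times[j]`.
#'
#' @param times Finite time vector (days), non-empty.
#' @param cfg A [basis_config()].
#' @return `length(times) x p` matrix.
#' @export
design_matrix <- function(times, cfg) {
  stopifnot(inherits(cfg, "basis_config"))
  if (length(times) == 0) {
    abort("times must be non-empty", class = "pp_domain_error")
  }
  if (any(!is.finite(times))) {
    abort("times must be finite", class = "pp_domain_error")
  }
  d2 <- outer(times, cfg$locations, function(t, phi) (t - phi)^2)
  cbind(1, exp(-cfg$bandwidth * d2))
}

#' Reconstruct a smooth curve from basis coefficients
#'
#' Evaluates `f(t) = b(t)' theta` over a time grid.
#'
#' @param theta Coefficient vector of length `p`.
#' @param grid Time grid (days).
#' @param cfg A [basis_config()].
#' @return Numeric vector of curve values, one per grid point.
#' @export
reconstruct_curve <- function(theta, grid, cfg) {
  stopifnot(inherits(cfg, "basis_config"))
  if (length(theta) != cfg$p) {
    abort("theta must have length p", class = "pp_dimension_error")
  }
  drop(design_matrix(grid, cfg) %*% theta)
}
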