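new_pp_curve <- function(df) {
  stopifnot(all(c("day", "mean", "lower", "upper") %in% names(df)))
  class(df) <- c("pp_curve", class(tibble::tibble()))
  df
}

curve_summary <- function(curve_draws, grid, extra = NULL) {
  # curve_draws: G x S matrix of per-draw curves
  df <- tibble::tibble(
    day = grid,
    mean = rowMeans(curve_draws),
    lower = apply(curve_draws, 1, quantile, probs = 0.025),
    upper = apply(curve_draws, 1, quantile, probs = 0.975)
  )
  if (!is.null(extra)) df <- dplyr::bind_cols(extra, df)
  new_pp_curve(df)
}

#' Posterior trajectory estimate for one athlete
#'
#' Reconstructs the athlete's smooth performance curve from every stored
#' posterior draw of their basis coefficients and summarizes pointwise:
#' posterior mean and 2.5/97.5% credible band. Bands widen over stretches
#' of the season where the athlete has no measurements.
#'
#' @param fit A `pp_fit`.
#' @param athlete_id Athlete identifier present in the fitted data.
#' @param grid Time grid in days; default 0..360.
#' @return A `pp_curve` tibble: `athlete_id`, `day`, `mean`, `lower`,
#'   `upper`.
#' @export
athlete_curve <- function(fit, athlete_id, grid = 0:360) {
  stopifnot(inherits(fit, "pp_fit"))
  i <- match(as.character(athlete_id), fit$ids)
  if (is.na(i)) {
    abort(paste0("unknown athlete: ", athlete_id), class = "pp_lookup_error")
  }
  Bg <- design_matrix(grid, fit$basis)
  th <- fit$draws$theta[i, , , drop = TRUE]           # p x S
  if (is.null(dim(th))) th <- matrix(th, ncol = fit$n_draws)
  curve_summary(Bg %*% th + fit$y_center, grid,
                extra = tibble::tibble(athlete_id = as.character(athlete_id)))
}

#' Group-averaged performance curves
#'
#' For each group (doped / clean), averages the basis coefficients over
#' group members — `theta_hat_g = mean of theta_hat_i over i in g` — and
#' reconstructs `f_hat_g(t) = b(t)' theta_hat_g`. The 95% band comes from
#' the per-draw group coefficient means, so the point curve equals the
#' posterior mean of the per-draw group curves (linearity).
#'
#' @param fit A `pp_fit`.
#' @param grid Time grid in days.
#' @return A `pp_curve` tibble with a `group` column (`"doped"`,
#'   `"clean"`).
#' @export
group_mean_curves <- function(fit, grid = 0:360) {
  stopifnot(inherits(fit, "pp_fit"))
  Bg <- design_matrix(grid, fit$basis)
  out <- list()
  for (g in c("doped", "clean")) {
    members <- which(fit$z == (g == "doped"))
    if (length(members) == 0) {
      abort(paste0("empty group: ", g), class = "pp_validation_error")
    }
    # per-draw group mean coefficients: p x S
    th <- fit$draws$theta[members, , , drop = FALSE]
    gm <- apply(th, c(2, 3), mean)
    out[[g]] <- curve_summary(Bg %*% gm + fit$y_center, grid,
                              extra = tibble::tibble(group = g))
  }
  new_pp_curve(dplyr::bind_rows(out))
}

#' Covariate-induced mean trajectory
#'
#' The model implies each athlete's curve is a Gaussian process with mean
#' `E[f_i(t)] = sum_m (beta' x_i)_m phitilde_m(t)` where
#' `phitilde_m(t) = sum_l lambda_lm b_l(t)`; equivalently
#' `b(t)' Lambda beta' x_i`. This evaluates that mean per posterior draw
#' for a given covariate vector and summarizes with a 95% band —
#' e.g. the expected trajectory of a 23-year-old male.
#'
#' @param fit A `pp_fit`.
#' @param x Covariate vector of length `r` on the encoded scale
#'   (`intercept`, `male`, `age_std`), or output of
#'   [encode_covariate_vector()].
#' @param grid Time grid in days.
#' @param center Add the fit's result-level offset so curves sit on the
#'   meter scale of the data (default). With `center = FALSE` the pure
#'   covariate-induced component `b(t)' Lambda beta' x` is returned,
#'   which is identically zero when `beta = 0`.
#' @return A `pp_curve` tibble.
#' @export
induced_mean_function <- function(fit, x, grid = 0:360, center = TRUE) {
  stopifnot(inherits(fit, "pp_fit"))
  r <- dim(fit$draws$beta)[1]
  if (length(x) != r) {
    abort("x must have length r", class = "pp_dimension_error")
  }
  Bg <- design_matrix(grid, fit$basis)
  S <- fit$n_draws
  curves <- matrix(0, length(grid), S)
  for (s in seq_len(S)) {
    bx <- drop(t(fit$draws$beta[, , s]) %*% x)          # k
    curves[, s] <- Bg %*% (fit$draws$Lambda[, , s] %*% bx)
  }
  if (center) curves <- curves + fit$y_center
  curve_summary(curves, grid)
}

#' Encode a single covariate vector on the fitted scale
#'
#' Builds `x = (1, male, age_std)` using the age standardization stored in
#' a fit, for use with [induced_mean_function()].
#'
#' @param fit A `pp_fit`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @return Numeric covariate vector of length 3.
#' @export
encode_covariate_vector <- function(fit, sex, age) {
  if (!sex %in% c("male", "female")) {
    abort("unknown sex label", class = "pp_validation_error")
  }
  c(1, as.numeric(sex == "male"), (age - fit$age_center) / fit$age_scale)
}

#' Induced covariance function of the trajectory process
#'
#' For one posterior state, the model-implied covariance
#' `Cov(f_i(s), f_i(t)) = sum_m phitilde_m(s) phitilde_m(t) +
#' sum_l sigma2_l b_l(s) b_l(t) = b(s)' (Lambda Lambda' + diag(sigma2))
#' b(t)`, symmetric and positive semi-definite.
#'
#' @param s,t Times in days (scalars or equal-length vectors; recycled
#'   pairwise).
#' @param Lambda `p x k` loading matrix.
#' @param sigma2 Length-`p` variance vector.
#' @param basis A [basis_config()].
#' @return Numeric vector of covariances.
#' @export
induced_covariance <- function(s, t, Lambda, sigma2, basis) {
  if (nrow(Lambda) != basis$p || length(sigma2) != basis$p) {
    abort("Lambda/sigma2 dimensions must match basis p",
          class = "pp_dimension_error")
  }
  n <- max(length(s), length(t))
  s <- rep_len(s, n)
  t <- rep_len(t, n)
  Bs <- design_matrix(s, basis)
  Bt <- design_matrix(t, basis)
  K <- tcrossprod(Lambda) + diag(sigma2, basis$p)
  rowSums((Bs %*% K) * Bt)
}
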