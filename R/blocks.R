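#' Single Gibbs full-conditional draws
#'
#' Thin wrappers around the compiled full-conditional updates used inside
#' [fit_passport()], exposed so the conditional algebra of each block can
#' be exercised (and verified) in isolation at fixed conditioning values.
#' All of them advance R's RNG, so draws are reproducible under
#' [set.seed()].
#'
#' @param data Results tibble.
#' @param basis A [basis_config()].
#' @param Lambda `p x k` loading matrix.
#' @param eta `n x k` latent factor matrix.
#' @param sigma2 Length-`p` positive vector of basis-coefficient residual
#'   variances.
#' @param psi2 Positive observation noise variance.
#' @param theta `n x p` basis coefficient matrix.
#' @param beta Covariate coefficient matrix (`r` rows, `k` columns).
#' @param X `n x r` covariate matrix.
#' @param gamma Length-`k` probit coefficient vector.
#' @param alpha Probit intercept.
#' @param u Length-`n` latent utility vector.
#' @param use_probit Include the probit information in the `eta`
#'   conditional?
#' @param prior A [prior_spec()] (scale hyperparameters).
#' @param prior_prec `p x k` matrix of loading prior precisions.
#' @param z Integer 0/1 doping indicators.
#' @name gibbs-blocks
NULL

#' @describeIn gibbs-blocks Draw each athlete's basis coefficients
#'   `theta_i` from the normal full conditional combining the athlete's
#'   data likelihood with the `N_p(Lambda eta_i, diag(sigma2))` prior
#'   (prior alone when the athlete has no records).
#' @export
draw_theta <- function(data, basis, Lambda, eta, sigma2, psi2) {
  if (psi2 <= 0) abort("psi2 must be positive", class = "pp_domain_error")
  ds <- as_pp_dataset(data)
  B <- design_matrix(ds$t, basis)
  out <- cpp_draw_theta(ds$y, ds$offsets, B, Lambda, eta, sigma2, psi2)
  rownames(out) <- ds$ids
  out
}

#' @describeIn gibbs-blocks Draw latent factors `eta_i` from the normal
#'   full conditional combining the `theta_i` likelihood, the
#'   `N_k(beta' x_i, I)` prior, and (optionally) the probit utility.
#' @export
draw_factors <- function(theta, Lambda, sigma2, beta, X, gamma = NULL,
                         alpha = 0, u = NULL, use_probit = FALSE) {
  k <- ncol(Lambda)
  if (is.null(gamma)) gamma <- rep(0, k)
  if (is.null(u)) u <- rep(0, nrow(theta))
  cpp_draw_eta(theta, Lambda, sigma2, beta, X, gamma, alpha, u, use_probit)
}

#' @describeIn gibbs-blocks Draw the loading matrix rows and the variance
#'   parameters (`sigma2_l`, `psi2` when data are supplied) from their
#'   normal / inverse-gamma full conditionals. Returns a list.
#' @export
draw_loadings_and_variances <- function(theta, eta, sigma2, prior_prec,
                                        prior = prior_spec(), data = NULL,
                                        basis = NULL) {
  Lambda <- cpp_draw_loadings(theta, eta, sigma2, prior_prec)
  sigma2_new <- cpp_draw_sigma2(theta, eta, Lambda, prior$a_sigma,
                                prior$b_sigma)
  psi2_new <- NULL
  if (!is.null(data)) {
    ds <- as_pp_dataset(data)
    B <- design_matrix(ds$t, basis)
    psi2_new <- cpp_draw_psi2(ds$y, ds$offsets, B, theta, prior$a_psi,
                              prior$b_psi)
  }
  list(Lambda = Lambda, sigma2 = sigma2_new, psi2 = psi2_new)
}

#' @describeIn gibbs-blocks Albert–Chib probit block: draw truncated-normal
#'   latent utilities consistent with `z`, then `(alpha, gamma)` jointly
#'   from their normal full conditional. Returns a list.
#' @export
draw_probit <- function(eta, z, alpha, gamma, prior = prior_spec()) {
  u <- cpp_draw_utilities(eta, alpha, gamma, as.integer(z))
  k <- ncol(eta)
  coef <- cpp_draw_probit_coefs(eta, u,
                                c(1 / prior$alpha_var, rep(1, k)),
                                c(prior$alpha_mean, rep(0, k)))
  list(alpha = coef$alpha, gamma = drop(coef$gamma), u = u)
}

#' @describeIn gibbs-blocks Draw the covariate coefficient matrix `beta`
#'   column-wise from its normal full conditional under N(0, 1) entry
#'   priors.
#' @export
draw_covariate_coefs <- function(eta, X) {
  cpp_draw_beta(eta, X)
}
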