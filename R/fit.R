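#' Fit the athlete performance passport model
#'
#' Runs the Gibbs sampler for the full hierarchical model: kernel basis
#' expansion of each athlete's trajectory (observation noise `psi2`),
#' sparse latent factor model `theta_i = Lambda eta_i + zeta_i` on the
#' basis coefficients, covariate regression `eta_i = beta' x_i + Delta_i`,
#' and an Albert–Chib probit for doping status
#' `P(z_i = 1) = Phi(alpha + gamma' eta_i)`. The cycle per iteration is
#' theta, eta, loadings/variances, covariate regression, probit.
#'
#' Results are centered internally (their grand mean is subtracted) so
#' the N(0, 1) priors on the covariate coefficients act on a sensible
#' scale; all curve summaries and predictions restore the offset, which
#' is stored as `y_center`.
#'
#' @param data Results tibble (see [read_results_csv()] /
#'   [generate_dataset()]).
#' @param basis A [basis_config()]; default [default_basis()] over the
#'   observed time span.
#' @param k Number of latent factors (`1 <= k < p`), default 5.
#' @param prior A [prior_spec()].
#' @param iterations,burnin,thin MCMC controls; defaults 10000 / 5000 / 5.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param likelihood If `FALSE`, runs the prior-recovery
#'   (Geweke successive-conditional) chain: the data term is dropped and
#'   latent trajectories are resampled from the model, so every
#'   parameter's marginal stationary distribution is its prior.
#' @param response If `FALSE`, drops the probit conditioning (utilities
#'   resampled from the model, `z` ignored).
#' @return A `pp_fit` object: posterior draw arrays (`theta` `[n, p, S]`,
#'   `Lambda` `[p, k, S]`, `eta` `[n, k, S]`, `beta` `[r, k, S]`,
#'   `sigma2` `[p, S]`, `gamma` `[k, S]`, `alpha`, `psi2`, `loglik` `[S]`),
#'   the basis, the athlete table, and run metadata.
#' @examples
#' sim <- generate_dataset(sim_config(n_athletes = 25, seed = 1))
#' fit <- fit_passport(sim$data, basis = sim$truth$basis, k = 2,
#'                     iterations = 300, burnin = 100, thin = 2, seed = 1)
#' glance(fit)
#' @export
fit_passport <- function(data, basis = NULL, k = 5, prior = prior_spec(),
                         iterations = 10000, burnin = 5000, thin = 5,
                         seed = NULL, likelihood = TRUE, response = TRUE) {
  if (is.null(seed)) {
    abort("seed is mandatory for a reproducible fit",
          class = "pp_config_error")
  }
  stopifnot(inherits(prior, "prior_spec"))
  if (burnin < 0 || iterations <= burnin || thin < 1) {
    abort("need iterations > burnin >= 0 and thin >= 1",
          class = "pp_config_error")
  }
  ds <- as_pp_dataset(data)
  if (nrow(ds$records) == 0) {
    abort("data is empty", class = "pp_validation_error")
  }
  if (is.null(basis)) basis <- default_basis(max(ds$t_max, 1))
  stopifnot(inherits(basis, "basis_config"))
  p <- basis$p
  if (k < 1 || k >= p) abort("need 1 <= k < p", class = "pp_config_error")
  B <- design_matrix(ds$t, basis)
  # center the results so the standard-normal priors on beta are on the
  # right scale; the offset is restored in every curve/prediction summary
  y_center <- mean(ds$y)
  ds$y <- ds$y - y_center

  # deterministic ridge initialization of theta
  theta_init <- matrix(0, length(ds$ids), p)
  for (i in seq_along(ds$ids)) {
    lo <- ds$offsets[i] + 1L
    hi <- ds$offsets[i + 1L]
    if (hi < lo) next
    Bi <- B[lo:hi, , drop = FALSE]
    theta_init[i, ] <- solve(crossprod(Bi) + diag(p),
                             crossprod(Bi, ds$y[lo:hi]))
  }

  set.seed(seed)
  raw <- cpp_fit(ds$y, ds$offsets, B, ds$X, ds$z, as.integer(k),
                 prior$a_sigma, prior$b_sigma, prior$a_psi, prior$b_psi,
                 prior$alpha_mean, prior$alpha_var,
                 prior$shrinkage == "mgp", prior$mgp_nu, prior$mgp_a1,
                 prior$mgp_a2,
                 as.integer(iterations), as.integer(burnin),
                 as.integer(thin), likelihood, response, theta_init)

  for (nm in c("alpha", "psi2", "loglik")) raw[[nm]] <- drop(raw[[nm]])
  structure(list(
    draws = raw[c("theta", "Lambda", "eta", "beta", "sigma2", "gamma",
                  "alpha", "psi2", "loglik")],
    n_draws = raw$n_draws,
    basis = basis, k = as.integer(k), prior = prior,
    athletes = ds$athletes, records = ds$records, ids = ds$ids,
    offsets = ds$offsets, y = ds$y, y_center = y_center, B = B, X = ds$X,
    z = ds$z,
    age_center = attr(ds$athletes, "age_center"),
    age_scale = attr(ds$athletes, "age_scale"),
    mcmc = list(iterations = iterations, burnin = burnin, thin = thin,
                seed = seed, likelihood = likelihood, response = response)
  ), class = "pp_fit")
}

#' @export
print.pp_fit <- function(x, ...) {
  cat("Athlete performance passport fit\n")
  cat("  athletes:", length(x$ids), " observations:", length(x$y), "\n")
  cat("  basis p =", x$basis$p, " factors k =", x$k, "\n")
  cat("  draws:", x$n_draws, "(", x$mcmc$iterations, "iterations, burn-in",
      x$mcmc$burnin, ", thin", x$mcmc$thin, ", seed", x$mcmc$seed, ")\n")
  cat("  posterior mean psi2:", signif(mean(x$draws$psi2), 4),
      " implied prevalence Phi(alpha):",
      signif(mean(pnorm(x$draws$alpha)), 4), "\n")
  invisible(x)
}

#' Tidy posterior summaries of shared parameters
#'
#' One row per scalar shared parameter (`psi2`, `alpha`, the implied
#' prevalence `Phi(alpha)`, each `gamma_m`, each `beta[r, m]`): posterior
#' mean, SD, and central 95% credible interval.
#'
#' @param x A `pp_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.pp_fit <- function(x, ...) {
  d <- x$draws
  mats <- list(psi2 = matrix(d$psi2, ncol = 1),
               alpha = matrix(d$alpha, ncol = 1),
               prevalence = matrix(pnorm(d$alpha), ncol = 1))
  gnames <- paste0("gamma_", seq_len(x$k))
  for (m in seq_len(x$k)) mats[[gnames[m]]] <- matrix(d$gamma[m, ], ncol = 1)
  covs <- c("intercept", "male", "age_std")
  for (m in seq_len(x$k)) {
    for (j in seq_len(dim(d$beta)[1])) {
      mats[[paste0("beta_", covs[j], "_", m)]] <-
        matrix(d$beta[j, m, ], ncol = 1)
    }
  }
  purrr::imap_dfr(mats, function(v, nm) {
    tibble::tibble(term = nm, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
}

#' One-row fit summary
#'
#' @param x A `pp_fit`.
#' @param ... Unused.
#' @return A tibble: athlete/observation counts, basis and factor sizes,
#'   number of stored draws, and the posterior mean log-likelihood.
#' @export
glance.pp_fit <- function(x, ...) {
  tibble::tibble(
    n_athletes = length(x$ids), n_obs = length(x$y), p = x$basis$p,
    k = x$k, n_draws = x$n_draws,
    mean_loglik = mean(x$draws$loglik),
    psi2 = mean(x$draws$psi2)
  )
}

#' Observation-model log likelihood
#'
#' Sum over all records of the Gaussian log density of `y_ij` at mean
#' `b(t_ij)' theta_i` and variance `psi2`.
#'
#' @param data Results tibble.
#' @param theta `n x p` coefficient matrix (athlete rows in the order of
#'   `sort(unique(athlete_id))`).
#' @param psi2 Positive observation noise variance.
#' @param basis A [basis_config()].
#' @return Scalar log likelihood.
#' @export
pp_log_likelihood <- function(data, theta, psi2, basis) {
  if (!is.finite(psi2) || psi2 <= 0) {
    abort("psi2 must be positive", class = "pp_domain_error")
  }
  ds <- as_pp_dataset(data)
  B <- design_matrix(ds$t, basis)
  cpp_log_likelihood(ds$y, ds$offsets, B, theta, psi2)
}

#' Probit doping probability
#'
#' `P(z = 1 | alpha, gamma, eta) = Phi(alpha + gamma' eta)`.
#'
#' @param alpha Probit intercept.
#' @param gamma Coefficient vector (length `k`).
#' @param eta Latent factor vector (length `k`).
#' @return Probability in (0, 1).
#' @export
doping_probability <- function(alpha, gamma, eta) {
  if (length(gamma) != length(eta)) {
    abort("gamma and eta must have the same length",
          class = "pp_dimension_error")
  }
  pnorm(alpha + sum(gamma * eta))
}
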