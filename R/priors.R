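#' Conjugate prior specification
#'
#' All priors are conditionally conjugate so every Gibbs block has a
#' closed-form full conditional:
#' * `sigma2_l` ~ inverse-gamma(1, 0.02): prior median ~0.03 m², matching
#'   the sub-meter scatter expected of basis coefficients on the centered
#'   meter scale;
#' * `psi2` ~ inverse-gamma(1, 0.05): prior median ~0.07 m², i.e. about
#'   0.27 m competition-to-competition noise;
#' * entries of `beta` and `gamma` ~ N(0, 1);
#' * probit intercept `alpha ~ N(qnorm(prevalence), alpha_var)` — the
#'   prior mean is elicited from an assumed population doping prevalence
#'   (default 1%), so `Phi(E[alpha])` equals the expert prevalence guess;
#' * loadings `Lambda`: multiplicative gamma process (MGP) column
#'   shrinkage (`shrinkage = "mgp"`, hyperparameters `mgp_a1`, `mgp_a2`,
#'   local-scale df `mgp_nu`) which prunes unneeded basis directions, or a
#'   plain N(0, 1) entry prior (`shrinkage = "normal"`).
#'
#' @param a_sigma,b_sigma Inverse-gamma shape/rate for each `sigma2_l`.
#' @param a_psi,b_psi Inverse-gamma shape/rate for the observation noise
#'   variance `psi2`.
#' @param prevalence Prior doping prevalence in (0, 1) setting the probit
#'   intercept prior mean `qnorm(prevalence)`.
#' @param alpha_var Prior variance of the probit intercept.
#' @param shrinkage `"mgp"` (default) or `"normal"`.
#' @param mgp_nu,mgp_a1,mgp_a2 MGP hyperparameters (local-scale gamma df
#'   and the two global increment shapes).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(a_sigma = 1, b_sigma = 0.02, a_psi = 1, b_psi = 0.05,
                       prevalence = 0.01, alpha_var = 1,
                       shrinkage = c("mgp", "normal"),
                       mgp_nu = 3, mgp_a1 = 2, mgp_a2 = 3) {
  shrinkage <- match.arg(shrinkage)
  vals <- c(a_sigma, b_sigma, a_psi, b_psi, alpha_var, mgp_nu, mgp_a1,
            mgp_a2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all prior scale/shape hyperparameters must be positive",
          class = "pp_config_error")
  }
  if (prevalence <= 0 || prevalence >= 1) {
    abort("prevalence must be in (0, 1)", class = "pp_config_error")
  }
  structure(list(a_sigma = a_sigma, b_sigma = b_sigma, a_psi = a_psi,
                 b_psi = b_psi, prevalence = prevalence,
                 alpha_mean = qnorm(prevalence), alpha_var = alpha_var,
                 shrinkage = shrinkage, mgp_nu = mgp_nu, mgp_a1 = mgp_a1,
                 mgp_a2 = mgp_a2),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Conjugate priors: psi2 ~ IG(", x$a_psi, ",", x$b_psi, "), sigma2_l ~ IG(",
      x$a_sigma, ",", x$b_sigma, "); beta, gamma ~ N(0,1)\n")
  cat("alpha ~ N(qnorm(", x$prevalence, ") = ", signif(x$alpha_mean, 4),
      ", ", x$alpha_var, "); loadings: ", x$shrinkage, "\n", sep = "")
  invisible(x)
}
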