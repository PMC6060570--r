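// Gibbs sampler for the latent factor performance-passport model.
//
// Model (athlete i, observation j):
//   y_ij = b(t_ij)' theta_i + eps_ij,        eps_ij ~ N(0, psi2)
//   theta_i = Lambda eta_i + zeta_i,         zeta_i ~ N_p(0, diag(sigma2))
//   eta_i   = beta' x_i + Delta_i,           Delta_i ~ N_k(0, I)
//   z_i ~ Bernoulli(Phi(alpha + gamma' eta_i))   (probit, Albert-Chib
//        augmentation u_i ~ N(alpha + gamma' eta_i, 1), z_i = 1{u_i > 0})
//
// All randomness goes through R's RNG so set.seed() gives bit-identical
// draws. Every full-conditional block is exported individually (cpp_draw_*)
// and the fit loop (cpp_fit) calls the same functions.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// numerical helpers
// ---------------------------------------------------------------------------

// Cholesky (upper) with jitter escalation 1e-8 -> 1e-4 (x10 steps).
// Throws after escalation fails; `block` names the offending Gibbs block.
static arma::mat chol_jitter(const arma::mat& P, const char* block) {
  arma::mat R;
  if (arma::chol(R, P)) return R;
  double scale = arma::mean(P.diag());
  if (!(scale > 0)) scale = 1.0;
  for (double jit = 1e-8; jit <= 1e-4 * 1.0000001; jit *= 10.0) {
    arma::mat Pj = P + jit * scale * arma::eye(P.n_rows, P.n_cols);
    if (arma::chol(R, Pj)) {
      Rcpp::warning("jitter %g applied in block '%s'", jit, block);
      return R;
    }
  }
  stop("Cholesky factorization failed in block '%s' after jitter escalation",
       block);
}

// Draw x ~ N(P^{-1} v, P^{-1}) given precision P and linear term v.
static arma::vec mvn_precision(const arma::mat& P, const arma::vec& v,
                               const char* block) {
  arma::mat R = chol_jitter(P, block);          // P = R'R, R upper
  arma::vec mean = arma::solve(arma::trimatl(R.t()), v);
  mean = arma::solve(arma::trimatu(R), mean);
  arma::vec zraw(P.n_rows);
  for (arma::uword d = 0; d < P.n_rows; ++d) zraw(d) = R::norm_rand();
  return mean + arma::solve(arma::trimatu(R), zraw);
}

static double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ InvGamma(shape, rate)
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

// N(mean, 1) truncated to (0, Inf). Inverse-CDF in the easy region,
// Robert (1995) exponential rejection when the region is a far upper tail
// (mean << 0), so extreme linear predictors never return +/-Inf.
// [[Rcpp::export]]
double cpp_rtnorm_pos(double mean) {
  double a = -mean;                       // draw std normal z > a, return mean + z
  double z;
  if (a < 5.0) {
    double pa = R::pnorm(a, 0.0, 1.0, 1, 0);
    double u = R::unif_rand();
    double q = pa + u * (1.0 - pa);
    if (q >= 1.0) q = 1.0 - 1e-16;
    z = R::qnorm(q, 0.0, 1.0, 1, 0);
    if (std::isfinite(z) && z > a) return mean + z;
    // fall through to rejection if inverse CDF degenerates
  }
  double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (int it = 0; it < 10000; ++it) {
    double e = R::exp_rand() / lambda;
    z = a + e;
    double rho = std::exp(-0.5 * (z - lambda) * (z - lambda));
    if (R::unif_rand() <= rho) return mean + z;
  }
  return mean + a + 1.0 / lambda;          // expected tail value, never Inf
}

// ---------------------------------------------------------------------------
// full-conditional blocks
// ---------------------------------------------------------------------------

// theta_i | y_i, Lambda, eta_i, Sigma, psi2 ~
//   N( P^{-1}(B_i'y_i/psi2 + Sigma^{-1} Lambda eta_i), P^{-1} ),
//   P = B_i'B_i/psi2 + Sigma^{-1}.  Athletes without observations draw
//   from the prior N(Lambda eta_i, Sigma).
// offsets: length n+1, 0-based row boundaries of each athlete in y/B.
// [[Rcpp::export]]
arma::mat cpp_draw_theta(const arma::vec& y, const arma::ivec& offsets,
                         const arma::mat& B, const arma::mat& Lambda,
                         const arma::mat& eta, const arma::vec& sigma2,
                         double psi2) {
  const int n = offsets.n_elem - 1;
  const int p = B.n_cols;
  if (psi2 <= 0) stop("psi2 must be positive");
  arma::mat theta(n, p);
  arma::vec sig_inv = 1.0 / sigma2;
  arma::mat prior_mean = eta * Lambda.t();   // n x p
  for (int i = 0; i < n; ++i) {
    int lo = offsets(i), hi = offsets(i + 1);
    if (hi == lo) {
      for (int l = 0; l < p; ++l)
        theta(i, l) = prior_mean(i, l) + std::sqrt(sigma2(l)) * R::norm_rand();
      continue;
    }
    arma::mat Bi = B.rows(lo, hi - 1);
    arma::vec yi = y.subvec(lo, hi - 1);
    arma::mat P = Bi.t() * Bi / psi2;
    P.diag() += sig_inv;
    arma::vec v = Bi.t() * yi / psi2 + sig_inv % prior_mean.row(i).t();
    theta.row(i) = mvn_precision(P, v, "theta").t();
  }
  return theta;
}

// eta_i | theta_i, Lambda, Sigma, beta, x_i [, u_i, alpha, gamma] ~
//   N(P^{-1} v, P^{-1}),  P = I_k + Lambda'Sigma^{-1}Lambda [+ gamma gamma'],
//   v = beta'x_i + Lambda'Sigma^{-1}theta_i [+ gamma (u_i - alpha)].
// The probit term is included only when use_probit is true (training
// athletes with observed z; held-out prediction omits it).
// [[Rcpp::export]]
arma::mat cpp_draw_eta(const arma::mat& theta, const arma::mat& Lambda,
                       const arma::vec& sigma2, const arma::mat& beta,
                       const arma::mat& X, const arma::vec& gamma,
                       double alpha, const arma::vec& u, bool use_probit) {
  const int n = theta.n_rows;
  const int k = Lambda.n_cols;
  arma::mat LtSi = Lambda.t() * arma::diagmat(1.0 / sigma2);  // k x p
  arma::mat P = arma::eye(k, k) + LtSi * Lambda;
  if (use_probit) P += gamma * gamma.t();
  arma::mat R = chol_jitter(P, "eta");
  arma::mat V = X * beta + theta * LtSi.t();                   // n x k
  if (use_probit) V += (u - alpha) * gamma.t();
  // means: solve P M' = V'
  arma::mat M = arma::solve(arma::trimatl(R.t()), V.t());
  M = arma::solve(arma::trimatu(R), M);                        // k x n
  arma::mat Z(k, n);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < k; ++l) Z(l, i) = R::norm_rand();
  arma::mat draws = M + arma::solve(arma::trimatu(R), Z);
  return draws.t();
}

// Row l of Lambda | theta, eta, sigma2_l under N(0, prior_prec(l,m)^{-1})
// entrywise priors:  P_l = diag(prior_prec row l) + eta'eta / sigma2_l,
// v_l = eta' theta_(.l) / sigma2_l.
// [[Rcpp::export]]
arma::mat cpp_draw_loadings(const arma::mat& theta, const arma::mat& eta,
                            const arma::vec& sigma2,
                            const arma::mat& prior_prec) {
  const int p = theta.n_cols;
  const int k = eta.n_cols;
  arma::mat EtE = eta.t() * eta;
  arma::mat Lambda(p, k);
  for (int l = 0; l < p; ++l) {
    arma::mat P = EtE / sigma2(l);
    P.diag() += prior_prec.row(l).t();
    arma::vec v = eta.t() * theta.col(l) / sigma2(l);
    Lambda.row(l) = mvn_precision(P, v, "loadings").t();
  }
  return Lambda;
}

// sigma2_l | theta, Lambda, eta ~ InvGamma(a + n/2, b + RSS_l/2)
// [[Rcpp::export]]
arma::vec cpp_draw_sigma2(const arma::mat& theta, const arma::mat& eta,
                          const arma::mat& Lambda, double a, double b) {
  const int n = theta.n_rows;
  const int p = theta.n_cols;
  arma::mat resid = theta - eta * Lambda.t();
  arma::vec out(p);
  for (int l = 0; l < p; ++l) {
    double rss = arma::dot(resid.col(l), resid.col(l));
    out(l) = rinvgamma(a + 0.5 * n, b + 0.5 * rss);
  }
  return out;
}

// psi2 | y, theta ~ InvGamma(a + N/2, b + RSS/2)
// [[Rcpp::export]]
double cpp_draw_psi2(const arma::vec& y, const arma::ivec& offsets,
                     const arma::mat& B, const arma::mat& theta,
                     double a, double b) {
  const int n = offsets.n_elem - 1;
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    int lo = offsets(i), hi = offsets(i + 1);
    if (hi == lo) continue;
    arma::vec r = y.subvec(lo, hi - 1) -
      B.rows(lo, hi - 1) * theta.row(i).t();
    rss += arma::dot(r, r);
  }
  return rinvgamma(a + 0.5 * y.n_elem, b + 0.5 * rss);
}

// Albert-Chib latent utilities: u_i ~ N(alpha + gamma'eta_i, 1) truncated
// to (0, Inf) if z_i = 1, (-Inf, 0] if z_i = 0.
// [[Rcpp::export]]
arma::vec cpp_draw_utilities(const arma::mat& eta, double alpha,
                             const arma::vec& gamma, const arma::ivec& z) {
  const int n = eta.n_rows;
  arma::vec lin = alpha + eta * gamma;
  arma::vec u(n);
  for (int i = 0; i < n; ++i) {
    u(i) = (z(i) == 1) ? cpp_rtnorm_pos(lin(i)) : -cpp_rtnorm_pos(-lin(i));
  }
  return u;
}

// (alpha, gamma) | u, eta: Bayesian linear regression of u on W = [1, eta]
// with unit noise; independent normal priors N(prior_mean, 1/prior_prec).
// [[Rcpp::export]]
List cpp_draw_probit_coefs(const arma::mat& eta, const arma::vec& u,
                           const arma::vec& prior_prec,
                           const arma::vec& prior_mean) {
  const int n = eta.n_rows;
  const int k = eta.n_cols;
  arma::mat W(n, k + 1, arma::fill::ones);
  if (k > 0) W.cols(1, k) = eta;
  arma::mat P = W.t() * W;
  P.diag() += prior_prec;
  arma::vec v = W.t() * u + prior_prec % prior_mean;
  arma::vec coef = mvn_precision(P, v, "probit");
  return List::create(_["alpha"] = coef(0),
                      _["gamma"] = arma::vec(coef.tail(k)));
}

// Columns of beta | eta, X with N(0,1) entry priors (residual cov of eta
// is I_k, so columns are conditionally independent with shared precision
// I_r + X'X).
// [[Rcpp::export]]
arma::mat cpp_draw_beta(const arma::mat& eta, const arma::mat& X) {
  const int r = X.n_cols;
  const int k = eta.n_cols;
  arma::mat P = X.t() * X;
  P.diag() += 1.0;
  arma::mat beta(r, k);
  for (int m = 0; m < k; ++m) {
    beta.col(m) = mvn_precision(P, X.t() * eta.col(m), "beta");
  }
  return beta;
}

// Multiplicative gamma process hyperparameter updates. Returns new
// (phi, delta, tau). lambda: p x k, phi: p x k local precisions,
// delta: k global increments, tau_m = prod_{h<=m} delta_h.
// [[Rcpp::export]]
List cpp_update_mgp(const arma::mat& Lambda, arma::mat phi, arma::vec delta,
                    double nu, double a1, double a2) {
  const int p = Lambda.n_rows;
  const int k = Lambda.n_cols;
  arma::vec tau = arma::cumprod(delta);
  arma::mat L2 = Lambda % Lambda;
  for (int l = 0; l < p; ++l)
    for (int m = 0; m < k; ++m)
      phi(l, m) = R::rgamma(0.5 * (nu + 1.0),
                            1.0 / (0.5 * (nu + tau(m) * L2(l, m))));
  for (int h = 0; h < k; ++h) {
    double shape = (h == 0 ? a1 : a2) + 0.5 * p * (k - h);
    double rate = 1.0;
    for (int m = h; m < k; ++m) {
      double tau_mh = tau(m) / delta(h);   // product excluding delta_h
      rate += 0.5 * tau_mh * arma::dot(phi.col(m), L2.col(m));
    }
    delta(h) = R::rgamma(shape, 1.0 / rate);
    tau = arma::cumprod(delta);
  }
  return List::create(_["phi"] = phi, _["delta"] = delta, _["tau"] = tau);
}

// Gaussian log likelihood of y given theta, psi2 (Eq. 1 sum).
// [[Rcpp::export]]
double cpp_log_likelihood(const arma::vec& y, const arma::ivec& offsets,
                          const arma::mat& B, const arma::mat& theta,
                          double psi2) {
  if (psi2 <= 0) stop("psi2 must be positive");
  const int n = offsets.n_elem - 1;
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    int lo = offsets(i), hi = offsets(i + 1);
    if (hi == lo) continue;
    arma::vec r = y.subvec(lo, hi - 1) -
      B.rows(lo, hi - 1) * theta.row(i).t();
    rss += arma::dot(r, r);
  }
  double N = y.n_elem;
  return -0.5 * N * std::log(2.0 * M_PI * psi2) - 0.5 * rss / psi2;
}

static void check_finite(const arma::mat& M, int iter, const char* block) {
  if (!M.is_finite())
    stop("non-finite state at iteration %d in block '%s'", iter + 1, block);
}

// ---------------------------------------------------------------------------
// full Gibbs loop
// ---------------------------------------------------------------------------
// flags: use_likelihood = FALSE runs the Geweke successive-conditional
// (prior-recovery) chain: theta/psi2 drawn from their model distributions
// with no data term. use_response = FALSE drops the probit conditioning
// (utilities drawn untruncated, z ignored).
// shrink_mgp = FALSE uses plain N(0,1) loading priors.
// [[Rcpp::export]]
List cpp_fit(const arma::vec& y, const arma::ivec& offsets,
             const arma::mat& B, const arma::mat& X, const arma::ivec& z,
             int k,
             double a_sigma, double b_sigma, double a_psi, double b_psi,
             double alpha_prior_mean, double alpha_prior_var,
             bool shrink_mgp, double mgp_nu, double mgp_a1, double mgp_a2,
             int iterations, int burnin, int thin,
             bool use_likelihood, bool use_response,
             const arma::mat& theta_init) {
  const int n = offsets.n_elem - 1;
  const int p = B.n_cols;
  const int r = X.n_cols;
  const int S = (iterations - burnin) / thin;

  // state
  arma::mat theta = theta_init;
  arma::mat Lambda(p, k, arma::fill::zeros);
  for (int m = 0; m < std::min(p, k); ++m) Lambda(m, m) = 0.1;
  arma::mat eta(n, k, arma::fill::zeros);
  arma::vec sigma2(p, arma::fill::ones);
  double psi2 = 1.0;
  arma::mat beta(r, k, arma::fill::zeros);
  arma::vec gamma(k, arma::fill::zeros);
  double alpha = alpha_prior_mean;
  arma::vec u(n, arma::fill::zeros);
  arma::mat phi(p, k, arma::fill::ones);
  arma::vec delta(k, arma::fill::ones);
  arma::vec tau = arma::cumprod(delta);

  arma::vec probit_prior_prec(k + 1, arma::fill::ones);
  probit_prior_prec(0) = 1.0 / alpha_prior_var;
  arma::vec probit_prior_mean(k + 1, arma::fill::zeros);
  probit_prior_mean(0) = alpha_prior_mean;

  // storage
  arma::cube theta_s(n, p, S), Lambda_s(p, k, S), eta_s(n, k, S),
    beta_s(r, k, S);
  arma::mat sigma2_s(p, S), gamma_s(k, S);
  arma::vec alpha_s(S), psi2_s(S), loglik_s(S);

  int kept = 0;
  for (int it = 0; it < iterations; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();

    // -- theta block
    if (use_likelihood) {
      theta = cpp_draw_theta(y, offsets, B, Lambda, eta, sigma2, psi2);
    } else {
      theta = eta * Lambda.t();
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < p; ++l)
          theta(i, l) += std::sqrt(sigma2(l)) * R::norm_rand();
    }
    check_finite(theta, it, "theta");

    // -- eta block
    eta = cpp_draw_eta(theta, Lambda, sigma2, beta, X, gamma, alpha, u,
                       use_response);
    check_finite(eta, it, "eta");

    // -- loadings / variances block
    arma::mat prior_prec(p, k);
    if (shrink_mgp) {
      for (int l = 0; l < p; ++l)
        for (int m = 0; m < k; ++m) prior_prec(l, m) = phi(l, m) * tau(m);
    } else {
      prior_prec.ones();
    }
    Lambda = cpp_draw_loadings(theta, eta, sigma2, prior_prec);
    check_finite(Lambda, it, "loadings");
    if (shrink_mgp) {
      List mg = cpp_update_mgp(Lambda, phi, delta, mgp_nu, mgp_a1, mgp_a2);
      phi = as<arma::mat>(mg["phi"]);
      delta = as<arma::vec>(mg["delta"]);
      tau = as<arma::vec>(mg["tau"]);
    }
    sigma2 = cpp_draw_sigma2(theta, eta, Lambda, a_sigma, b_sigma);
    psi2 = use_likelihood
      ? cpp_draw_psi2(y, offsets, B, theta, a_psi, b_psi)
      : rinvgamma(a_psi, b_psi);
    if (!std::isfinite(psi2) || !sigma2.is_finite())
      stop("non-finite state at iteration %d in block 'variances'", it + 1);

    // -- covariate regression block
    beta = cpp_draw_beta(eta, X);
    check_finite(beta, it, "beta");

    // -- probit block
    if (use_response) {
      u = cpp_draw_utilities(eta, alpha, gamma, z);
    } else {
      arma::vec lin = alpha + eta * gamma;
      for (int i = 0; i < n; ++i) u(i) = lin(i) + R::norm_rand();
    }
    List coef = cpp_draw_probit_coefs(eta, u, probit_prior_prec,
                                      probit_prior_mean);
    alpha = as<double>(coef["alpha"]);
    gamma = as<arma::vec>(coef["gamma"]);
    if (!std::isfinite(alpha) || !gamma.is_finite())
      stop("non-finite state at iteration %d in block 'probit'", it + 1);

    // -- store
    if (it >= burnin && (it - burnin) % thin == 0 && kept < S) {
      theta_s.slice(kept) = theta;
      Lambda_s.slice(kept) = Lambda;
      eta_s.slice(kept) = eta;
      beta_s.slice(kept) = beta;
      sigma2_s.col(kept) = sigma2;
      gamma_s.col(kept) = gamma;
      alpha_s(kept) = alpha;
      psi2_s(kept) = psi2;
      loglik_s(kept) = use_likelihood
        ? cpp_log_likelihood(y, offsets, B, theta, psi2) : NA_REAL;
      ++kept;
    }
  }

  return List::create(
    _["theta"] = theta_s, _["Lambda"] = Lambda_s, _["eta"] = eta_s,
    _["beta"] = beta_s, _["sigma2"] = sigma2_s, _["gamma"] = gamma_s,
    _["alpha"] = alpha_s, _["psi2"] = psi2_s, _["loglik"] = loglik_s,
    _["n_draws"] = kept);
}

// ---------------------------------------------------------------------------
// held-out prediction
// ---------------------------------------------------------------------------
// For each posterior draw s and each test athlete i, draw eta_i from its
// exact conditional given records y_i and covariates x_i only ("cut"
// prediction, no probit term): marginalizing theta_i,
//   y_i | eta_i ~ N(B_i Lambda eta_i, psi2 I + B_i diag(sigma2) B_i'),
//   eta_i ~ N(beta'x_i, I)  =>  Gaussian posterior; then evaluate
// Phi(alpha_s + gamma_s' eta_i). Returns n_test x S probability matrix.
// [[Rcpp::export]]
arma::mat cpp_predict_probs(const arma::vec& y, const arma::ivec& offsets,
                            const arma::mat& B, const arma::mat& X,
                            const arma::cube& Lambda_s,
                            const arma::mat& sigma2_s,
                            const arma::vec& psi2_s,
                            const arma::cube& beta_s,
                            const arma::mat& gamma_s,
                            const arma::vec& alpha_s) {
  const int n = offsets.n_elem - 1;
  const int S = Lambda_s.n_slices;
  const int k = Lambda_s.n_cols;
  arma::mat probs(n, S);
  for (int s = 0; s < S; ++s) {
    const arma::mat& Lambda = Lambda_s.slice(s);
    const arma::mat betam = beta_s.slice(s);
    arma::vec sigma2 = sigma2_s.col(s);
    double psi2 = psi2_s(s);
    arma::vec gamma = gamma_s.col(s);
    double alpha = alpha_s(s);
    arma::mat prior_mean_all = X * betam;    // n x k
    for (int i = 0; i < n; ++i) {
      int lo = offsets(i), hi = offsets(i + 1);
      arma::vec eta_i;
      if (hi == lo) {
        eta_i = prior_mean_all.row(i).t();
        for (int m = 0; m < k; ++m) eta_i(m) += R::norm_rand();
      } else {
        arma::mat Bi = B.rows(lo, hi - 1);
        arma::vec yi = y.subvec(lo, hi - 1);
        arma::mat A = Bi * Lambda;                       // n_i x k
        arma::mat C = Bi * arma::diagmat(sigma2) * Bi.t();
        C.diag() += psi2;
        arma::mat Cinv_A = arma::solve(C, A, arma::solve_opts::likely_sympd);
        arma::mat P = arma::eye(k, k) + A.t() * Cinv_A;
        arma::vec v = prior_mean_all.row(i).t() +
          Cinv_A.t() * yi;
        eta_i = mvn_precision(P, v, "predict");
      }
      double lin = alpha + arma::dot(gamma, eta_i);
      probs(i, s) = R::pnorm(lin, 0.0, 1.0, 1, 0);
    }
  }
  return probs;
}
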