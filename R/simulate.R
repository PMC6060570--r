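#' Synthetic shot put season configuration
#'
#' Defines the generative conditions for a synthetic elite shot put
#' season with the shape of the 2012 cohort the model targets:
#' 352 athletes, 3.69% with a career doping conviction, 1–27 measurements
#' per athlete (mean 9.34) spread irregularly over a ~360-day season,
#' ages 15–43 (mean 23), 175/352 male, and a doped-vs-clean performance
#' gap of about 1 m. Trajectories are drawn from the model's own
#' generative structure (basis expansion, latent factors, covariate
#' regression, Gaussian noise).
#'
#' Default true parameters (chosen for realism of elite shot put): overall
#' level 17 m, male effect +0.8 m, +0.4 m per SD of age; factor 1 loads
#' only on the constant basis element (athlete level, loading 0.4 so the
#' covariate-adjusted athlete-to-athlete level SD is ~0.4 m); factor 2
#' loads on the kernels with alternating sign (within-season shape,
#' ~±0.4 m); small independent coefficient wiggle (`sigma2`); and
#' competition-to-competition noise SD 0.5 m (`psi2 = 0.25`).
#'
#' @param n_athletes Number of athletes (default 352).
#' @param doped_fraction Fraction with a doping conviction (default
#'   0.0369).
#' @param doped_shift_m Constant upward shift of doped athletes' smooth
#'   curves, meters (default 1).
#' @param shift_onset_day If non-`NULL`, the shift ramps linearly from 0
#'   at this day to full size at season end instead of being constant.
#' @param meas_q Success probability of the measurement-count law
#'   `1 + Binomial(26, meas_q)` (support 1..27); default `8.34/26` so the
#'   mean is 9.34.
#' @param season_length_days Season length (default 360).
#' @param times Sampling-time mode: `"uniform"` days over the season, or
#'   `"clustered"` — competition weekends a few days apart, mimicking the
#'   real calendar's short-range clustering.
#' @param age_range,age_mean Age support and mean; ages are drawn from a
#'   Beta distribution rescaled to the range with the requested mean.
#' @param male_fraction Fraction of male athletes (default 175/352).
#' @param doping_mode `"exact"` assigns exactly
#'   `round(n * doped_fraction)` doped athletes at random (mirrors the
#'   fixed 13/352); `"probit"` draws `z_i ~ Bernoulli(Phi(alpha* +
#'   gamma*' eta_i))` with `alpha* = qnorm(doped_fraction)` for
#'   end-to-end probit recovery tests.
#' @param gamma_star True probit coefficients for `doping_mode =
#'   "probit"`.
#' @param basis True [basis_config()]; default `default_basis(season,
#'   p = 8)`.
#' @param Lambda,beta,sigma2,psi2 True model parameters; defaults as
#'   described above.
#' @param seed RNG seed (default 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_athletes = 352, doped_fraction = 0.0369,
                       doped_shift_m = 1, shift_onset_day = NULL,
                       meas_q = 8.34 / 26, season_length_days = 360,
                       times = c("uniform", "clustered"),
                       age_range = c(15, 43), age_mean = 23,
                       male_fraction = 175 / 352,
                       doping_mode = c("exact", "probit"),
                       gamma_star = NULL,
                       basis = NULL, Lambda = NULL, beta = NULL,
                       sigma2 = NULL, psi2 = 0.25, seed = 1) {
  times <- match.arg(times)
  doping_mode <- match.arg(doping_mode)
  if (n_athletes < 1) abort("n_athletes must be >= 1",
                            class = "pp_config_error")
  if (doped_fraction < 0 || doped_fraction > 1) {
    abort("doped_fraction must be in [0, 1]", class = "pp_config_error")
  }
  if (doped_shift_m < 0) abort("doped_shift_m must be >= 0",
                               class = "pp_config_error")
  if (meas_q < 0 || meas_q > 1) abort("meas_q must be in [0, 1]",
                                      class = "pp_config_error")
  mean_count <- 1 + 26 * meas_q
  if (mean_count < 1 || mean_count > 27) {
    abort("measurement-count mean must lie in [1, 27]",
          class = "pp_config_error")
  }
  if (!is.null(shift_onset_day) &&
      (shift_onset_day < 0 || shift_onset_day > season_length_days)) {
    abort("shift_onset_day outside the season", class = "pp_config_error")
  }
  if (is.null(basis)) basis <- default_basis(season_length_days, p = 8)
  p <- basis$p
  if (is.null(Lambda)) {
    Lambda <- matrix(0, p, 2)
    Lambda[1, 1] <- 0.4
    if (p > 1) Lambda[2:p, 2] <- 0.35 * (-1)^(2:p)
  }
  k <- ncol(Lambda)
  if (is.null(beta)) {
    # factor 1 maps to the f level through Lambda[1,1] = 0.4, so these are
    # (17, 0.8, 0.4) meters on the result scale
    beta <- matrix(0, 3, k)
    beta[, 1] <- c(17, 0.8, 0.4) / Lambda[1, 1]
    if (k >= 2) beta[3, 2] <- 0.3
  }
  if (is.null(sigma2)) sigma2 <- c(0.01, rep(0.04, p - 1))
  if (is.null(gamma_star)) gamma_star <- rep(0, k)
  if (any(sigma2 <= 0) || psi2 < 0) {
    abort("variance parameters must be positive", class = "pp_config_error")
  }
  structure(list(
    n_athletes = as.integer(n_athletes), doped_fraction = doped_fraction,
    doped_shift_m = doped_shift_m, shift_onset_day = shift_onset_day,
    meas_q = meas_q, season_length_days = season_length_days,
    times = times, age_range = age_range, age_mean = age_mean,
    male_fraction = male_fraction, doping_mode = doping_mode,
    gamma_star = gamma_star, basis = basis, Lambda = Lambda, beta = beta,
    sigma2 = sigma2, psi2 = psi2, seed = seed
  ), class = "sim_config")
}

#' Draw per-athlete measurement counts
#'
#' Counts follow `1 + Binomial(26, q)`: support 1..27 with mean
#' `1 + 26 q` (9.34 at the default `q`), matching the observed range and
#' mean of measurements per athlete in an elite season.
#'
#' @param n Number of athletes.
#' @param q Binomial success probability.
#' @return Integer vector of counts in `[1, 27]`.
#' @export
generate_measurement_counts <- function(n, q = 8.34 / 26) {
  if (q < 0 || q > 1) abort("q must be in [0, 1]", class = "pp_config_error")
  1L + rbinom(n, 26L, q)
}

#' Apply a doping effect to true curves
#'
#' Raises doped athletes' smooth curves by `shift_m` meters — constant
#' over the season by default, or ramping linearly from 0 at
#' `onset_day` to the full shift at season end. The shift acts on the
#' underlying performance curve, not on the measurement noise; a constant
#' shift is absorbed into the constant-basis coefficient `theta_1`.
#'
#' @param truth Ground-truth list from [generate_dataset()] (fields
#'   `theta`, `f_grid`, `grid`, `z`, `basis`, `season_length_days`).
#' @param shift_m Shift size in meters (`>= 0`).
#' @param onset_day `NULL` for a constant shift, else the ramp onset day.
#' @return The modified truth list.
#' @export
inject_doping_effect <- function(truth, shift_m, onset_day = NULL) {
  if (shift_m < 0) abort("shift_m must be >= 0", class = "pp_config_error")
  season <- truth$season_length_days
  if (!is.null(onset_day) && (onset_day < 0 || onset_day > season)) {
    abort("onset_day outside the season", class = "pp_config_error")
  }
  doped <- truth$z == 1
  if (!any(doped) || shift_m == 0) return(truth)
  if (is.null(onset_day)) {
    truth$theta[doped, 1] <- truth$theta[doped, 1] + shift_m
    truth$f_grid[doped, ] <- truth$f_grid[doped, ] + shift_m
    truth$shift <- function(t) rep(shift_m, length(t))
  } else {
    ramp <- function(t) {
      shift_m * pmax(0, pmin(1, (t - onset_day) / (season - onset_day)))
    }
    truth$f_grid[doped, ] <- truth$f_grid[doped, ] +
      matrix(ramp(truth$grid), sum(doped), length(truth$grid), byrow = TRUE)
    truth$shift <- ramp
  }
  truth
}

#' Generate a synthetic season
#'
#' Draws a full synthetic dataset from the model's generative structure
#' under a [sim_config()]: covariates (sex, age), doping status, latent
#' factors `eta_i = beta*' x_i + Delta_i`, basis coefficients
#' `theta_i = Lambda* eta_i + zeta_i`, irregular observation times, and
#' noisy results `y_ij = b(t_ij)' theta_i + eps_ij`; doped athletes'
#' curves are raised by the configured shift. Deterministic under the
#' config seed.
#'
#' @param cfg A [sim_config()].
#' @return A list: `data` (results tibble in the canonical CSV schema,
#'   plus `t`, `age`) and `truth` (true parameters, per-athlete `eta`,
#'   `theta`, `z`, true curves `f_grid` on `grid`, and the athlete
#'   table).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_athletes
  p <- cfg$basis$p
  k <- ncol(cfg$Lambda)
  season <- cfg$season_length_days

  sex <- ifelse(runif(n) < cfg$male_fraction, "male", "female")
  # Beta(a, b) rescaled to age_range with mean age_mean
  mu <- (cfg$age_mean - cfg$age_range[1]) / diff(cfg$age_range)
  a_beta <- 2
  b_beta <- a_beta * (1 - mu) / mu
  age <- cfg$age_range[1] + diff(cfg$age_range) * rbeta(n, a_beta, b_beta)

  age_std <- (age - mean(age)) / stats::sd(age)
  X <- cbind(intercept = 1, male = as.numeric(sex == "male"),
             age_std = age_std)

  eta <- X %*% cfg$beta +
    matrix(rnorm(n * k), n, k)
  if (cfg$doping_mode == "exact") {
    n_doped <- floor(n * cfg$doped_fraction + 0.5)
    if (cfg$doped_fraction > 0 && n_doped == 0) {
      abort("doped_fraction rounds to zero doped athletes",
            class = "pp_config_error")
    }
    z <- integer(n)
    z[sample.int(n, n_doped)] <- 1L
  } else {
    # gamma* acts on the centered factors so that alpha* = qnorm(fraction)
    # keeps the configured marginal prevalence
    alpha_star <- qnorm(cfg$doped_fraction)
    eta_c <- sweep(eta, 2, colMeans(eta))
    pz <- pnorm(alpha_star + drop(eta_c %*% cfg$gamma_star))
    z <- as.integer(runif(n) < pz)
  }

  zeta <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(cfg$sigma2), p)
  theta <- eta %*% t(cfg$Lambda) + zeta

  grid <- seq(0, season, by = 5)
  truth <- list(
    config = cfg, basis = cfg$basis, Lambda = cfg$Lambda, beta = cfg$beta,
    sigma2 = cfg$sigma2, psi2 = cfg$psi2, eta = eta, theta = theta, z = z,
    grid = grid,
    f_grid = theta %*% t(design_matrix(grid, cfg$basis)),
    season_length_days = season,
    athletes = tibble::tibble(
      athlete_id = sprintf("ath%04d", seq_len(n)), sex = sex, age = age,
      doped = z
    )
  )
  truth <- inject_doping_effect(truth, cfg$doped_shift_m,
                                cfg$shift_onset_day)
  theta <- truth$theta

  counts <- generate_measurement_counts(n, cfg$meas_q)
  season_start <- as.Date("2012-01-05")
  rows <- vector("list", n)
  shift_fun <- truth$shift
  for (i in seq_len(n)) {
    if (cfg$times == "uniform") {
      days <- sort(sample.int(season, counts[i], replace = TRUE) - 1L)
    } else {
      # competition weekends: cluster centers + 0-3 day offsets
      n_clusters <- max(1L, ceiling(counts[i] / 3))
      centers <- sort(sample.int(season, n_clusters, replace = TRUE) - 1L)
      days <- sort(pmin(season - 1L,
                        centers[sample.int(n_clusters, counts[i],
                                           replace = TRUE)] +
                          sample(0:3, counts[i], replace = TRUE)))
    }
    t_i <- days - min(days)                 # per-athlete origin, t_i1 = 0
    f_i <- drop(design_matrix(t_i, cfg$basis) %*% theta[i, ])
    if (!is.null(shift_fun) && z[i] == 1 && !is.null(cfg$shift_onset_day)) {
      # ramped shift lives on f, not theta
      f_i <- f_i + shift_fun(t_i)
    }
    y_i <- f_i + sqrt(cfg$psi2) * rnorm(counts[i])
    rows[[i]] <- tibble::tibble(
      athlete_id = truth$athletes$athlete_id[i],
      sex = sex[i],
      birth_date = season_start + min(days) - round(age[i] * 365.25),
      event_date = season_start + days,
      result_m = round(y_i, 6),
      doped = z[i],
      t = as.numeric(t_i),
      age = age[i]
    )
  }
  data <- dplyr::bind_rows(rows)
  list(data = data, truth = truth)
}
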