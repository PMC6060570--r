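test_that("two fits with the same seed give identical draw sequences", {
  sim <- small_sim(n = 12, seed = 4)
  f1 <- fit_passport(sim$data, basis = sim$truth$basis, k = 2,
                     iterations = 120, burnin = 40, thin = 2, seed = 5)
  f2 <- fit_passport(sim$data, basis = sim$truth$basis, k = 2,
                     iterations = 120, burnin = 40, thin = 2, seed = 5)
  expect_identical(f1$draws$theta, f2$draws$theta)
  expect_identical(f1$draws$psi2, f2$draws$psi2)
  expect_identical(f1$draws$alpha, f2$draws$alpha)
})

test_that("stored draws respect the model's support and bookkeeping", {
  qf <- quick_fit()
  fit <- qf$fit
  expect_equal(fit$n_draws, (800 - 300) %/% 2)
  expect_true(all(fit$draws$psi2 > 0))
  expect_true(all(fit$draws$sigma2 > 0))
  expect_true(all(is.finite(fit$draws$loglik)))
  expect_equal(dim(fit$draws$theta), c(40, fit$basis$p, fit$n_draws))
  expect_equal(dim(fit$draws$Lambda), c(fit$basis$p, 2, fit$n_draws))
})

test_that("fit configuration is validated", {
  sim <- small_sim(n = 6, seed = 1)
  expect_error(fit_passport(sim$data, k = 2, iterations = 50, burnin = 10,
                            thin = 1), class = "pp_config_error")  # no seed
  expect_error(fit_passport(sim$data, basis = sim$truth$basis, k = 20,
                            iterations = 50, burnin = 10, seed = 1),
               class = "pp_config_error")                          # k >= p
  expect_error(fit_passport(sim$data, basis = sim$truth$basis, k = 2,
                            iterations = 50, burnin = 60, seed = 1),
               class = "pp_config_error")
})

test_that("tidy and glance summarize the posterior draws", {
  qf <- quick_fit()
  td <- tidy(qf$fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in%
                    names(td)))
  expect_true(all(c("psi2", "alpha", "prevalence", "gamma_1") %in% td$term))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  prev <- td$estimate[td$term == "prevalence"]
  expect_true(prev > 0 && prev < 1)
  gl <- glance(qf$fit)
  expect_equal(gl$n_athletes, 40)
  expect_equal(gl$n_draws, qf$fit$n_draws)
})

test_that("posterior psi2 concentrates near the generating value", {
  qf <- quick_fit()   # generated with psi2* = 0.25
  post_mean <- mean(qf$fit$draws$psi2)
  expect_gt(post_mean, 0.15)
  expect_lt(post_mean, 0.4)
})

test_that("curve of the posterior-mean coefficients equals the mean of
           per-draw curves (linearity identity)", {
  qf <- quick_fit()
  fit <- qf$fit
  grid <- seq(0, 360, by = 20)
  Bg <- design_matrix(grid, fit$basis)
  i <- 3
  theta_bar <- rowMeans(fit$draws$theta[i, , ])
  per_draw_mean <- rowMeans(Bg %*% fit$draws$theta[i, , ])
  expect_equal(drop(Bg %*% theta_bar), per_draw_mean, tolerance = 1e-10)
  # and athlete_curve's mean column agrees (on the meter scale)
  cv <- athlete_curve(fit, fit$ids[i], grid)
  expect_equal(cv$mean, per_draw_mean + fit$y_center, tolerance = 1e-10)
})

test_that("persisted draws reload to the same posterior summaries", {
  qf <- quick_fit()
  dir <- tempfile()
  write_draws(qf$fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_draws(dir)
  expect_equal(back$n_draws, qf$fit$n_draws)
  expect_equal(mean(back$draws$psi2), mean(qf$fit$draws$psi2),
               tolerance = 1e-6)
  expect_equal(back$draws$theta[2, 3, 5], qf$fit$draws$theta[2, 3, 5],
               tolerance = 1e-6)
  grid <- seq(0, 300, 50)
  expect_equal(athlete_curve(back, qf$fit$ids[2], grid)$mean,
               athlete_curve(qf$fit, qf$fit$ids[2], grid)$mean,
               tolerance = 1e-5)
})

test_that("induced-mean recovery sharpens as the cohort grows", {
  rmse_at_n <- function(n, seed) {
    sim <- generate_dataset(sim_config(n_athletes = n, doped_fraction = 0.1,
                                       seed = seed))
    fit <- fit_passport(sim$data, basis = sim$truth$basis, k = 2,
                        iterations = 1500, burnin = 600, thin = 3,
                        seed = seed + 1000)
    grid <- seq(0, 360, 10)
    Bg <- design_matrix(grid, sim$truth$basis)
    errs <- sapply(list(c("male", 23), c("female", 28)), function(sp) {
      x <- encode_covariate_vector(fit, sp[1], as.numeric(sp[2]))
      est <- induced_mean_function(fit, x, grid)$mean
      tru <- drop(Bg %*% (sim$truth$Lambda %*% (t(sim$truth$beta) %*% x)))
      sqrt(mean((est - tru)^2))
    })
    c(rmse = mean(errs), prev = mean(pnorm(fit$draws$alpha)))
  }
  res <- lapply(c(50, 150, 400), function(n)
    rowMeans(sapply(1:3, function(s) rmse_at_n(n, s))))
  rmse <- vapply(res, `[[`, numeric(1), "rmse")
  # seed-averaged error decreases monotonically from n = 50 to n = 400
  expect_true(all(diff(rmse) < 0))
  # implied prevalence at the largest cohort sits near the true 10%
  expect_gt(res[[3]][["prev"]], 0.02)
  expect_lt(res[[3]][["prev"]], 0.3)
})
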