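test_that("measurement counts follow 1 + Binomial(26, q)", {
  set.seed(20)
  expect_true(all(generate_measurement_counts(500, q = 0) == 1))
  expect_true(all(generate_measurement_counts(500, q = 1) == 27))
  counts <- generate_measurement_counts(1e5)
  expect_true(all(counts >= 1 & counts <= 27))
  # mean 1 + 26q = 9.34; SE of the sample mean ~ sqrt(26q(1-q)/1e5)
  expect_equal(mean(counts), 9.34, tolerance = 0.05 / 9.34)
  expect_error(generate_measurement_counts(10, q = 2),
               class = "pp_config_error")
})

test_that("generated cohorts match the configured population shape", {
  sim <- generate_dataset(sim_config(n_athletes = 10000, seed = 21))
  ath <- sim$truth$athletes
  n_per <- table(sim$data$athlete_id)
  expect_equal(mean(n_per), 9.34, tolerance = 0.01)
  expect_equal(mean(ath$sex == "male"), 175 / 352, tolerance = 0.02)
  expect_equal(mean(ath$age), 23, tolerance = 0.01)
  expect_true(all(ath$age >= 15 & ath$age <= 43))
  expect_equal(mean(ath$doped), 0.0369, tolerance = 1e-4)  # exact-count mode
  expect_true(all(sim$data$t >= 0 & sim$data$t <= 360))
  expect_true(all(sim$data$result_m > 0))
})

test_that("exact-count doping assignment reproduces the 13-of-352 balance", {
  sim <- generate_dataset(sim_config(n_athletes = 352, seed = 22))
  expect_equal(sum(sim$truth$z), 13)
  expect_error(generate_dataset(sim_config(n_athletes = 5,
                                           doped_fraction = 0.01)),
               class = "pp_config_error")
})

test_that("probit-mode doping assignment tracks Phi(alpha* + gamma*'eta)", {
  cfg <- sim_config(n_athletes = 20000, doped_fraction = 0.1,
                    doping_mode = "probit", doped_shift_m = 0, seed = 23)
  sim <- generate_dataset(cfg)
  # with gamma* = 0 the marginal prevalence is the configured fraction
  # (SE ~ 0.002 at n = 20000)
  expect_lt(abs(mean(sim$truth$z) - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
})

test_that("doping shift acts on the smooth curves, not the noise", {
  cfg0 <- sim_config(n_athletes = 80, doped_shift_m = 0, seed = 24)
  cfg1 <- sim_config(n_athletes = 80, doped_shift_m = 1, seed = 24)
  sim0 <- generate_dataset(cfg0)
  sim1 <- generate_dataset(cfg1)
  # same seed, zero shift: identical datasets
  expect_identical(generate_dataset(cfg0)$data, sim0$data)
  doped <- sim1$truth$z == 1
  # shifted truth differs from unshifted by exactly 1 m on doped curves
  expect_equal(sim1$truth$f_grid[doped, ] - sim0$truth$f_grid[doped, ],
               matrix(1, sum(doped), ncol(sim0$truth$f_grid)))
  expect_equal(sim1$truth$f_grid[!doped, ], sim0$truth$f_grid[!doped, ])
  # observed doped results shift with the curve (same noise draws)
  doped_ids <- sim1$truth$athletes$athlete_id[doped]
  d0 <- dplyr::filter(sim0$data, athlete_id %in% doped_ids)
  d1 <- dplyr::filter(sim1$data, athlete_id %in% doped_ids)
  expect_equal(d1$result_m - d0$result_m, rep(1, nrow(d0)), tolerance = 1e-5)
})

test_that("a mid-season ramp leaves the pre-onset gap at zero", {
  cfg <- sim_config(n_athletes = 200, doped_fraction = 0.2,
                    doped_shift_m = 1, shift_onset_day = 180, seed = 25)
  sim <- generate_dataset(cfg)
  tr <- sim$truth
  pre <- tr$grid <= 180
  gap_curve <- colMeans(tr$f_grid[tr$z == 1, , drop = FALSE]) -
    colMeans(tr$f_grid[tr$z == 0, , drop = FALSE])
  base_gap <- gap_curve[pre]           # sampling noise only, no shift
  expect_lt(max(abs(base_gap)), 0.3)
  expect_gt(gap_curve[length(gap_curve)], 0.5)
  expect_error(sim_config(shift_onset_day = 500), class = "pp_config_error")
})

test_that("the constant 1 m shift yields a ~1 m true group gap at the
           cohort scale", {
  gaps <- sapply(26:28, function(s) {
    tr <- generate_dataset(sim_config(n_athletes = 352, seed = s))$truth
    mean(tr$f_grid[tr$z == 1, ]) - mean(tr$f_grid[tr$z == 0, ])
  })
  # 13 doped athletes with ~0.7 m level SD: mean gap within 3 SE of 1 m
  expect_lt(abs(mean(gaps) - 1), 3 * 0.7 / sqrt(13 * 3))
})

test_that("generation is byte-identical on disk under a fixed config", {
  cfg <- sim_config(n_athletes = 12, doped_fraction = 0.25, seed = 29)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_results_csv(generate_dataset(cfg)$data, p1)
  write_results_csv(generate_dataset(cfg)$data, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("clustered sampling times stay within season and start at zero", {
  sim <- generate_dataset(sim_config(n_athletes = 50, times = "clustered",
                                     seed = 30))
  expect_true(all(sim$data$t >= 0 & sim$data$t <= 360))
  t0 <- dplyr::summarise(dplyr::group_by(sim$data, athlete_id),
                         t0 = min(t))$t0
  expect_true(all(t0 == 0))
})
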