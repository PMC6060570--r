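test_that("stratified split preserves the doped proportion by count", {
  # 2012 shot put shape: 352 athletes, 13 doped, 52 held out -> 2 doped
  sim <- generate_dataset(sim_config(n_athletes = 352, seed = 6))
  sp <- stratified_split(sim$data, n_test = 52, seed = 1)
  test_athletes <- dplyr::distinct(sp$test, athlete_id, doped)
  expect_equal(nrow(test_athletes), 52)
  expect_equal(sum(test_athletes$doped), 2)
  # the doped fraction of the full sample prints as 3.69%
  expect_equal(round(100 * 13 / 352, 2), 3.69)
})

test_that("split partitions athletes exactly once and is seed-stable", {
  sim <- small_sim(n = 30, seed = 8)
  sp1 <- stratified_split(sim$data, n_test = 10, seed = 3)
  sp2 <- stratified_split(sim$data, n_test = 10, seed = 3)
  expect_identical(sp1$manifest, sp2$manifest)
  ids_train <- unique(sp1$train$athlete_id)
  ids_test <- unique(sp1$test$athlete_id)
  expect_length(intersect(ids_train, ids_test), 0)
  expect_setequal(c(ids_train, ids_test), unique(sim$data$athlete_id))
  expect_equal(nrow(sp1$train) + nrow(sp1$test), nrow(sim$data))
  expect_error(stratified_split(sim$data, n_test = 30, seed = 1),
               class = "pp_config_error")
})

test_that("stratum rounding is half-up on the exact proportion", {
  # 10 athletes, 5 doped, 4 held out -> exactly 2 doped in test
  data <- tibble::tibble(
    athlete_id = sprintf("a%02d", 1:10), sex = "male", age = 25,
    doped = rep(c(1, 0), each = 5), t = 0, result_m = 18,
    event_date = as.Date("2012-06-01"), birth_date = as.Date("1987-01-01")
  )
  sp <- stratified_split(data, n_test = 4, seed = 2)
  expect_equal(sum(dplyr::distinct(sp$test, athlete_id, doped)$doped), 2)
  # all-clean data puts no doped athletes in test
  sp0 <- stratified_split(dplyr::mutate(data, doped = 0), n_test = 4,
                          seed = 2)
  expect_equal(sum(dplyr::distinct(sp0$test, athlete_id, doped)$doped), 0)
})

test_that("AUC equals brute-force pair enumeration, including ties", {
  # worked example: 3 of the 4 doped/clean pairs are concordant
  roc <- roc_auc(c(0.9, 0.4, 0.35, 0.8), c(1, 1, 0, 0))
  expect_equal(roc$auc, 0.75)
  # and enumerating the pairs directly for a mixed labeling
  expect_equal(roc_auc(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0))$auc, 0.5)
  expect_true(all(diff(roc$curve$tpr) >= 0))
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_equal(roc$curve$tpr[1], 0)
  expect_equal(max(roc$curve$tpr), 1)
  # random instances: exact match with the pairwise statistic
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 2)       # rounding forces ties
    ref <- {
      pos <- scores[labels == 1]; neg <- scores[labels == 0]
      pairs <- outer(pos, neg, function(a, b)
        (a > b) + 0.5 * (a == b))
      mean(pairs)
    }
    expect_equal(roc_auc(scores, labels)$auc, ref)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(13)
  scores <- runif(30)
  labels <- rbinom(30, 1, 0.3)
  labels[1] <- 1; labels[2] <- 0
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(qnorm(scores / 2 + 0.1), labels)$auc, a0)
  expect_equal(roc_auc(100 * scores^3, labels)$auc, a0)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- runif(40)
  labels <- c(1, 0, rbinom(38, 1, 0.3))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("degenerate score sets behave as defined", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 0))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), class = "pp_validation_error")
})

test_that("threshold classification is strict at the cutoff", {
  conf <- classify_at_threshold(c(0.6, 0.2), c(1, 0), 0.5)
  expect_equal(conf[, c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
  # a score exactly at the threshold is classified clean
  conf2 <- classify_at_threshold(c(0.5, 0.7), c(1, 1), 0.5)
  expect_equal(conf2$tp, 1L)
  expect_equal(conf2$fn, 1L)
  conf3 <- classify_at_threshold(rep(0, 5), c(1, 0, 0, 1, 0), 0.5)
  expect_equal(conf3$tp + conf3$fp, 0L)
  expect_error(classify_at_threshold(0.4, 1, 1.5), class = "pp_config_error")
})

test_that("held-out prediction separates strongly shifted doped athletes", {
  sim <- generate_dataset(sim_config(n_athletes = 60, doped_fraction = 0.1,
                                     doped_shift_m = 1.5, seed = 15))
  fit <- fit_passport(sim$data, basis = sim$truth$basis, k = 2,
                      iterations = 800, burnin = 300, thin = 2, seed = 16)
  pred <- predict_doping(fit, sim$data, seed = 17)
  z <- sim$truth$z[match(pred$athlete_id, sim$truth$athletes$athlete_id)]
  expect_gt(mean(pred$p_doped[z == 1]), mean(pred$p_doped[z == 0]))
  # deterministic under a fixed seed
  pred2 <- predict_doping(fit, sim$data, seed = 17)
  expect_identical(pred$p_doped, pred2$p_doped)
  expect_true(all(pred$p_doped > 0 & pred$p_doped < 1))
})

test_that("prediction with gamma = 0 draws collapses to Phi(alpha)", {
  qf <- quick_fit()
  fit <- qf$fit
  fit$draws$gamma <- fit$draws$gamma * 0
  pred <- predict_doping(fit, qf$sim$data, seed = 18)
  expect_equal(pred$p_doped,
               rep(mean(pnorm(fit$draws$alpha)), nrow(pred)),
               tolerance = 1e-12)
})
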