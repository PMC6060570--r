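#' Stratified train/test split of athletes
#'
#' Splits athletes (not records) into train and test sets preserving the
#' doped/clean proportion: the number of doped test athletes is
#' `round-half-up(n_test * n_doped / n)`, members drawn uniformly without
#' replacement within each stratum. With the 2012 shot put shape
#' (n = 352, 13 doped) and `n_test = 52` this puts exactly 2 doped
#' athletes in the test set.
#'
#' @param data Results tibble.
#' @param n_test Number of test athletes (`< n`).
#' @param seed RNG seed.
#' @return A list of class `pp_split`: `train`, `test` (results tibbles
#'   over disjoint athletes whose union is the input), `seed`, and a
#'   `manifest` tibble (`athlete_id`, `partition`).
#' @export
stratified_split <- function(data, n_test, seed) {
  athletes <- data |>
    dplyr::distinct(.data$athlete_id, .data$doped)
  n <- nrow(athletes)
  if (n_test >= n) {
    abort("n_test must be smaller than the number of athletes",
          class = "pp_config_error")
  }
  doped_ids <- athletes$athlete_id[athletes$doped == 1]
  clean_ids <- athletes$athlete_id[athletes$doped == 0]
  n_doped_test <- floor(n_test * length(doped_ids) / n + 0.5)  # round half up
  n_clean_test <- n_test - n_doped_test
  if (n_doped_test > length(doped_ids) || n_clean_test > length(clean_ids)) {
    abort("stratum too small for the requested test size",
          class = "pp_config_error")
  }
  set.seed(seed)
  test_ids <- c(sample(doped_ids, n_doped_test),
                sample(clean_ids, n_clean_test))
  manifest <- tibble::tibble(
    athlete_id = athletes$athlete_id,
    partition = ifelse(athletes$athlete_id %in% test_ids, "test", "train")
  )
  structure(list(
    train = dplyr::filter(data, !.data$athlete_id %in% test_ids),
    test = dplyr::filter(data, .data$athlete_id %in% test_ids),
    seed = seed, manifest = manifest
  ), class = "pp_split")
}

#' @export
print.pp_split <- function(x, ...) {
  n_tr <- dplyr::n_distinct(x$train$athlete_id)
  n_te <- dplyr::n_distinct(x$test$athlete_id)
  cat("Stratified split (seed", x$seed, "):", n_tr, "train /", n_te,
      "test athletes\n")
  invisible(x)
}

#' Predict held-out doping probabilities
#'
#' For each athlete in `newdata` and each posterior draw, samples the
#' athlete's latent factors from their exact conditional given only that
#' athlete's performance records and covariates — the probit term is
#' omitted because the doping status is unknown ("cut" prediction) — and
#' evaluates `Phi(alpha + gamma' eta)`. The reported score is the
#' across-draw mean of these probabilities (posterior predictive
#' averaging, not the probability at posterior-mean parameters). Athletes
#' with no records are predicted from covariates alone and flagged.
#'
#' @param fit A `pp_fit` (trained on the training athletes).
#' @param newdata Results tibble for held-out athletes (doping status is
#'   not used).
#' @param seed RNG seed for the conditional factor draws.
#' @return A tibble: `athlete_id`, `p_doped`, `n_records`,
#'   `covariates_only`.
#' @export
predict_doping <- function(fit, newdata, seed = 1) {
  stopifnot(inherits(fit, "pp_fit"))
  ds <- as_pp_dataset(newdata, age_center = fit$age_center,
                      age_scale = fit$age_scale)
  B <- design_matrix(ds$t, fit$basis)
  ds$y <- ds$y - fit$y_center     # training-set result-level offset
  set.seed(seed)
  probs <- cpp_predict_probs(ds$y, ds$offsets, B, ds$X,
                             fit$draws$Lambda, fit$draws$sigma2,
                             fit$draws$psi2, fit$draws$beta,
                             fit$draws$gamma, fit$draws$alpha)
  n_rec <- diff(ds$offsets)
  out <- tibble::tibble(
    athlete_id = ds$ids,
    p_doped = rowMeans(probs),
    n_records = as.integer(n_rec),
    covariates_only = n_rec == 0L
  )
  if (any(out$covariates_only)) {
    warn(paste0(sum(out$covariates_only),
                " athlete(s) predicted from covariates alone (no records)"))
  }
  out
}

#' ROC curve and AUC
#'
#' The AUC is the Mann–Whitney pairwise statistic: the probability that a
#' random doped athlete's score exceeds a random clean athlete's, with
#' ties counting 1/2. The curve enumerates all distinct score thresholds
#' (descending), classifying positive when `score > threshold`.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 truth, same length; both classes must appear.
#' @return A `pp_roc` list: `curve` tibble (`threshold`, `fpr`, `tpr`,
#'   both non-decreasing), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort("scores and labels must have the same length",
          class = "pp_dimension_error")
  }
  if (length(unique(labels)) < 2) {
    abort("AUC undefined: labels must contain both classes",
          class = "pp_validation_error")
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thresholds,
    tpr = vapply(thresholds, function(th) sum(scores > th & labels == 1),
                 numeric(1)) / n1,
    fpr = vapply(thresholds, function(th) sum(scores > th & labels == 0),
                 numeric(1)) / n0
  )
  structure(list(curve = curve, auc = auc), class = "pp_roc")
}

#' @export
print.pp_roc <- function(x, ...) {
  cat("ROC over", nrow(x$curve) - 1, "distinct thresholds; AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' Threshold classification with confusion counts
#'
#' Classifies doped when `score > threshold` — strictly greater, so a
#' score exactly at the threshold is classified clean.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 truth.
#' @param threshold Cutoff in (0, 1); default 0.5, the random
#'   classification rate.
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, plus a `predictions` list column with
#'   the 0/1 calls.
#' @export
classify_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must be in (0, 1)", class = "pp_config_error")
  }
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tibble::tibble(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
    specificity = ifelse(tn + fp > 0, tn / (tn + fp), NA_real_),
    predictions = list(pred)
  )
}
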