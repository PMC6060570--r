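#' Read a run configuration file
#'
#' Flat YAML document with optional sections `simulate` (keys of
#' [sim_config()]), `fit` (`p`, `k`, `iterations`, `burnin`, `thin`,
#' `prevalence`, `shrinkage`), and `split` (`n_test`, `seed`). Unknown
#' keys raise an error naming the key; missing keys fall back to package
#' defaults.
#'
#' @param path YAML file path.
#' @return A named list with `simulate`, `fit`, `split` sublists and
#'   `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "pp_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("seed", "simulate", "fit", "split")
  bad <- setdiff(names(raw), known_top)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "pp_config_error")
  }
  check_keys <- function(sec, allowed, name) {
    bad <- setdiff(names(sec), allowed)
    if (length(bad) > 0) {
      abort(paste0("unknown key(s) in '", name, "': ",
                   paste(bad, collapse = ", ")),
            class = "pp_config_error")
    }
    sec
  }
  sim_keys <- c("n_athletes", "doped_fraction", "doped_shift_m",
                "shift_onset_day", "meas_q", "season_length_days", "times",
                "male_fraction", "doping_mode", "psi2", "seed", "p")
  fit_keys <- c("p", "k", "iterations", "burnin", "thin", "prevalence",
                "shrinkage", "seed")
  split_keys <- c("n_test", "seed")
  list(
    seed = raw$seed %||% 1L,
    simulate = check_keys(raw$simulate %||% list(), sim_keys, "simulate"),
    fit = check_keys(raw$fit %||% list(), fit_keys, "fit"),
    split = check_keys(raw$split %||% list(), split_keys, "split")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(out_dir, seed, config, outputs) {
  missing_out <- outputs[!file.exists(file.path(out_dir, outputs))]
  if (length(missing_out) > 0) {
    abort(paste0("manifest lists missing output(s): ",
                 paste(missing_out, collapse = ", ")),
          class = "pp_io_error")
  }
  man <- list(seed = seed, timestamp = format(Sys.time(), tz = "UTC"),
              config_hash = config_hash(config), outputs = outputs)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(man)
}

#' Simulate a dataset to disk
#'
#' Writes `dataset.csv` (canonical schema), ground-truth sidecars
#' (`truth_theta.csv`, `truth_eta.csv`, `truth_params.yaml`), and a
#' manifest with the seed and config hash. Byte-identical across reruns
#' with the same config.
#'
#' @param config Path to a YAML run config, or a list from
#'   [read_run_config()].
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the config.
#' @return The generated dataset list, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  sim_args <- cfg$simulate
  p_override <- sim_args$p
  sim_args$p <- NULL
  if (!is.null(p_override)) {
    sim_args$basis <- default_basis(
      sim_args$season_length_days %||% 360, p = p_override)
  }
  sim_args$seed <- seed %||% sim_args$seed %||% cfg$seed
  sc <- do.call(sim_config, sim_args)
  sim <- generate_dataset(sc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_csv(sim$data, file.path(out_dir, "dataset.csv"))
  readr::write_csv(tibble::as_tibble(sim$truth$theta, .name_repair = "minimal"),
                   file.path(out_dir, "truth_theta.csv"))
  readr::write_csv(tibble::as_tibble(sim$truth$eta, .name_repair = "minimal"),
                   file.path(out_dir, "truth_eta.csv"))
  yaml::write_yaml(list(psi2 = sc$psi2, sigma2 = sc$sigma2,
                        Lambda = as.vector(sc$Lambda),
                        beta = as.vector(sc$beta),
                        n_doped = sum(sim$truth$z),
                        doped_fraction_pct = round(100 * mean(sim$truth$z), 2)),
                  file.path(out_dir, "truth_params.yaml"))
  write_manifest(out_dir, sc$seed, unclass(sc)[setdiff(names(sc), "basis")],
                 c("dataset.csv", "truth_theta.csv", "truth_eta.csv",
                   "truth_params.yaml"))
  invisible(sim)
}

#' Fit the model from a config and data file
#'
#' Reads the dataset, fits [fit_passport()] with the `fit` section of the
#' config, persists draws with [write_draws()] and writes a manifest.
#'
#' @param config Path to a YAML run config, or a parsed list.
#' @param data_path Dataset CSV path.
#' @param out_dir Output directory for the draw tables.
#' @param seed Optional seed overriding the config.
#' @return The `pp_fit`, invisibly.
#' @export
run_fit <- function(config, data_path, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  fc <- cfg$fit
  data <- read_results_csv(data_path)
  basis <- default_basis(max(data$t, 1), p = fc$p %||% 20)
  fit <- fit_passport(
    data, basis = basis, k = fc$k %||% 5,
    prior = prior_spec(prevalence = fc$prevalence %||% 0.01,
                       shrinkage = fc$shrinkage %||% "mgp"),
    iterations = fc$iterations %||% 10000, burnin = fc$burnin %||% 5000,
    thin = fc$thin %||% 5, seed = seed %||% fc$seed %||% cfg$seed)
  write_draws(fit, out_dir)
  invisible(fit)
}

#' Report figures and backing tables from a fit
#'
#' Emits the figure-level outputs of the analysis, each with a CSV twin
#' so every figure is regenerable from its table alone: per-athlete
#' trajectory estimates with 95% bands, the doped/clean group-mean
#' curves (suppressed with a warning when only one group is present),
#' covariate-effect trajectories (default: male athletes aged 15/23/30),
#' and — when `test_data` with known status is supplied — the ROC curve
#' and confusion counts at the 0.5 threshold.
#'
#' @param fit A `pp_fit` (or directory accepted by [read_draws()]).
#' @param out_dir Output directory.
#' @param athlete_ids Athletes to plot individually (default: first 6).
#' @param ages,sexes Covariate-effect curve settings.
#' @param test_data Optional held-out results tibble with `doped`.
#' @param grid Reporting grid (default days 0..360).
#' @param seed Seed for held-out prediction draws.
#' @return Invisible list of written file names.
#' @export
run_report <- function(fit, out_dir, athlete_ids = NULL,
                       ages = c(15, 23, 30), sexes = "male",
                       test_data = NULL, grid = 0:360, seed = 1) {
  if (is.character(fit)) fit <- read_draws(fit)
  stopifnot(inherits(fit, "pp_fit"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  save_pair <- function(df, plot, stem) {
    readr::write_csv(df, file.path(out_dir, paste0(stem, ".csv")))
    ggplot2::ggsave(file.path(out_dir, paste0(stem, ".png")), plot,
                    width = 7, height = 5, dpi = 120)
    outputs <<- c(outputs, paste0(stem, ".csv"), paste0(stem, ".png"))
  }

  if (is.null(athlete_ids)) athlete_ids <- utils::head(fit$ids, 6)
  ath <- dplyr::bind_rows(lapply(athlete_ids, athlete_curve, fit = fit,
                                 grid = grid))
  save_pair(ath, autoplot(new_pp_curve(ath)), "athlete_curves")

  if (!is.null(fit$z) && length(unique(fit$z)) == 2) {
    grp <- group_mean_curves(fit, grid)
    save_pair(grp, autoplot(grp), "group_mean_curves")
  } else {
    warn("group-mean plot suppressed: need both doped and clean athletes")
  }

  cov_curves <- dplyr::bind_rows(lapply(sexes, function(sx) {
    dplyr::bind_rows(lapply(ages, function(a) {
      cv <- induced_mean_function(
        fit, encode_covariate_vector(fit, sx, a), grid)
      dplyr::mutate(cv, group = paste0(sx, "_", a), .before = 1)
    }))
  }))
  save_pair(cov_curves, autoplot(new_pp_curve(cov_curves)),
            "covariate_effect_curves")

  if (!is.null(test_data)) {
    pred <- predict_doping(fit, test_data, seed = seed)
    labels <- test_data |>
      dplyr::distinct(.data$athlete_id, .data$doped)
    pred <- dplyr::left_join(pred, labels, by = "athlete_id")
    readr::write_csv(pred, file.path(out_dir, "predictions.csv"))
    outputs <- c(outputs, "predictions.csv")
    if (length(unique(pred$doped)) == 2) {
      roc <- roc_auc(pred$p_doped, pred$doped)
      save_pair(roc$curve, autoplot(roc), "roc")
      conf <- classify_at_threshold(pred$p_doped, pred$doped, 0.5)
      readr::write_csv(dplyr::select(conf, -"predictions"),
                       file.path(out_dir, "confusion_0.5.csv"))
      jsonlite::write_json(list(auc = roc$auc,
                                confusion = as.list(conf[1, 1:7])),
                           file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, "confusion_0.5.csv", "summary.json")
    }
  }
  write_manifest(out_dir, seed, list(athletes = athlete_ids, ages = ages),
                 outputs)
  invisible(outputs)
}
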