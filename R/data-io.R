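#' Read long-format competition results
#'
#' Reads a CSV of per-competition results (one row per attempt/result) and
#' returns a validated tibble with model time added. Required columns:
#' `athlete_id`, `sex` (`"male"`/`"female"`), `birth_date` (ISO-8601),
#' `event_date` (ISO-8601), `result_m` (meters, positive), `doped` (0/1,
#' constant within athlete).
#'
#' Model time `t` is the offset in days from each athlete's *own* first
#' event, so `t = 0` at every athlete's first record and calendar alignment
#' across athletes is not imposed; the calendar date is kept for plotting.
#' `age` is the athlete's age in years at their first event. Same-day
#' repeat results are kept with identical `t` (the observation-noise term
#' absorbs within-day variation).
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector remapping column names,
#'   e.g. `c(result_m = "distance")` if the file calls the result column
#'   `distance`.
#' @return A tibble with columns `athlete_id`, `sex`, `birth_date`,
#'   `event_date`, `result_m`, `doped`, `t`, `age`, sorted by athlete and
#'   `t`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_results_csv(generate_dataset(sim_config(n_athletes = 5))$data, path)
#' read_results_csv(path)
#' @export
read_results_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "pp_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  required <- c("athlete_id", "sex", "birth_date", "event_date",
                "result_m", "doped")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pp_schema_error")
  }
  validate_results(tibble::as_tibble(raw[required]))
}

validate_results <- function(raw) {
  parse_iso_date <- function(x, col) {
    d <- as.Date(vapply(x, function(s) {
      out <- tryCatch(as.character(as.Date(s, format = "%Y-%m-%d")),
                      error = function(e) NA_character_)
      if (is.na(out)) NA_character_ else out
    }, character(1)), format = "%Y-%m-%d")
    bad <- which(is.na(d) | is.na(x))
    if (length(bad) > 0) {
      abort(paste0("unparseable ", col, " at row(s): ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            class = "pp_row_error")
    }
    d
  }
  out <- tibble::tibble(
    athlete_id = as.character(raw$athlete_id),
    sex = tolower(as.character(raw$sex)),
    birth_date = parse_iso_date(raw$birth_date, "birth_date"),
    event_date = parse_iso_date(raw$event_date, "event_date"),
    result_m = suppressWarnings(as.numeric(raw$result_m)),
    doped = suppressWarnings(as.integer(raw$doped))
  )
  bad_sex <- which(!out$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex label at row(s): ",
                 paste(utils::head(bad_sex, 5), collapse = ", ")),
          class = "pp_row_error")
  }
  bad_res <- which(is.na(out$result_m) | out$result_m <= 0)
  if (length(bad_res) > 0) {
    abort(paste0("non-positive or unparseable result_m at row(s): ",
                 paste(utils::head(bad_res, 5), collapse = ", ")),
          class = "pp_row_error")
  }
  bad_z <- which(is.na(out$doped) | !out$doped %in% c(0L, 1L))
  if (length(bad_z) > 0) {
    abort(paste0("doped must be 0/1; bad row(s): ",
                 paste(utils::head(bad_z, 5), collapse = ", ")),
          class = "pp_row_error")
  }
  out |>
    dplyr::group_by(.data$athlete_id) |>
    dplyr::arrange(.data$event_date, .by_group = TRUE) |>
    dplyr::mutate(
      t = as.numeric(.data$event_date - min(.data$event_date)),
      age = as.numeric(min(.data$event_date) - .data$birth_date[1]) / 365.25
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$athlete_id, .data$t)
}

#' Write competition results to CSV
#'
#' Inverse of [read_results_csv()]: writes the canonical schema columns so
#' that reading the file back reproduces the same dataset (results round
#' trip to within floating point).
#'
#' @param data A results tibble (needs the canonical schema columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(data, path) {
  cols <- c("athlete_id", "sex", "birth_date", "event_date", "result_m",
            "doped")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "pp_schema_error")
  }
  readr::write_csv(data[cols], path)
  invisible(path)
}

#' Encode athlete-level covariates
#'
#' Collapses a results tibble to one row per athlete and builds the static
#' covariate design used by the latent factor regression:
#' `x_i = (1, male, age_std)` — an explicit intercept, a male indicator,
#' and age at first event standardized to zero mean / unit SD over the
#' dataset (three covariate columns, so `r` is 3).
#'
#' @param data Results tibble from [read_results_csv()] or
#'   [generate_dataset()].
#' @param age_center,age_scale Optional fixed centering/scaling (e.g. the
#'   training-set values when encoding a test set). Defaults to the sample
#'   mean/SD of `data`.
#' @return A tibble with one row per athlete: `athlete_id`, `sex`, `age`,
#'   `doped`, `n_records`, and covariate columns `intercept`, `male`,
#'   `age_std`; attributes `age_center` and `age_scale` record the
#'   standardization.
#' @export
encode_covariates <- function(data, age_center = NULL, age_scale = NULL) {
  if (!all(c("athlete_id", "sex", "age", "doped") %in% names(data))) {
    abort("data must have athlete_id, sex, age, doped columns",
          class = "pp_schema_error")
  }
  athletes <- data |>
    dplyr::group_by(.data$athlete_id) |>
    dplyr::summarise(
      sex = .data$sex[1], age = .data$age[1], doped = .data$doped[1],
      n_records = dplyr::n(), .groups = "drop"
    )
  if (any(!athletes$sex %in% c("male", "female"))) {
    abort("unknown sex label", class = "pp_validation_error")
  }
  if (any(athletes$age <= 0)) {
    abort("age must be positive", class = "pp_validation_error")
  }
  if (is.null(age_center)) age_center <- mean(athletes$age)
  if (is.null(age_scale)) age_scale <- stats::sd(athletes$age)
  if (is.na(age_scale) || age_scale == 0) age_scale <- 1
  out <- athletes |>
    dplyr::mutate(
      intercept = 1,
      male = as.numeric(.data$sex == "male"),
      age_std = (.data$age - age_center) / age_scale
    )
  attr(out, "age_center") <- age_center
  attr(out, "age_scale") <- age_scale
  out
}

# Internal: assemble the flat structures the compiled sampler consumes.
# Returns list(records, athletes, y, offsets, X, z, ids, t_max).
as_pp_dataset <- function(data, basis = NULL, age_center = NULL,
                          age_scale = NULL) {
  if (!all(c("athlete_id", "t", "result_m") %in% names(data))) {
    abort("data must have athlete_id, t, result_m columns",
          class = "pp_schema_error")
  }
  records <- dplyr::arrange(data, .data$athlete_id, .data$t)
  athletes <- encode_covariates(records, age_center, age_scale)
  ids <- unique(records$athlete_id)
  athletes <- athletes[match(ids, athletes$athlete_id), ]
  idx <- match(records$athlete_id, ids)
  counts <- tabulate(idx, nbins = length(ids))
  list(
    records = records,
    athletes = athletes,
    y = records$result_m,
    t = records$t,
    offsets = as.integer(c(0, cumsum(counts))),
    X = as.matrix(athletes[, c("intercept", "male", "age_std")]),
    z = as.integer(athletes$doped),
    ids = ids,
    t_max = max(records$t)
  )
}
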