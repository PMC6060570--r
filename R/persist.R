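#' Persist posterior draws as flat tables
#'
#' Writes one CSV per parameter block (draw index x flattened parameter,
#' column names encoding the array position, e.g. `theta_i3_p2`) plus a
#' `manifest.json` with seed, dimensions, iteration counts, and a hash of
#' the fit configuration. No binary formats.
#'
#' @param fit A `pp_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "pp_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(a, row_lab, col_lab) {
    if (length(dim(a)) == 3) {
      m <- t(apply(a, 3, as.vector))
      idx <- expand.grid(i = seq_len(dim(a)[1]), j = seq_len(dim(a)[2]))
      colnames(m) <- paste0(row_lab, idx$i, "_", col_lab, idx$j)
    } else {
      m <- t(a)
      colnames(m) <- paste0(row_lab, seq_len(nrow(a)))
    }
    tibble::as_tibble(m)
  }
  tabs <- list(
    theta = flat(fit$draws$theta, "i", "p"),
    Lambda = flat(fit$draws$Lambda, "p", "k"),
    eta = flat(fit$draws$eta, "i", "k"),
    beta = flat(fit$draws$beta, "r", "k"),
    sigma2 = flat(fit$draws$sigma2, "p"),
    gamma = flat(fit$draws$gamma, "k"),
    scalars = tibble::tibble(alpha = fit$draws$alpha,
                             psi2 = fit$draws$psi2,
                             loglik = fit$draws$loglik)
  )
  for (nm in names(tabs)) {
    tab <- dplyr::mutate(tabs[[nm]], draw = dplyr::row_number(),
                         .before = 1)
    readr::write_csv(tab, file.path(dir, paste0(nm, ".csv")))
  }
  cfg <- list(
    n_athletes = length(fit$ids), n_obs = length(fit$y),
    p = fit$basis$p, k = fit$k, n_draws = fit$n_draws,
    basis_locations = fit$basis$locations,
    basis_bandwidth = fit$basis$bandwidth,
    age_center = fit$age_center, age_scale = fit$age_scale,
    y_center = fit$y_center %||% 0,
    ids = fit$ids, mcmc = fit$mcmc
  )
  cfg$config_hash <- config_hash(cfg)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Reload persisted draws
#'
#' Reads a directory written by [write_draws()] back into a `pp_fit`-like
#' object carrying the draw arrays, basis, and metadata (sufficient for
#' curve summaries and prediction).
#'
#' @param dir Directory written by [write_draws()].
#' @return A `pp_fit` object (without the original records/design).
#' @export
read_draws <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  S <- man$n_draws
  p <- man$p
  k <- man$k
  n <- man$n_athletes
  get <- function(nm) {
    as.matrix(readr::read_csv(file.path(dir, paste0(nm, ".csv")),
                              show_col_types = FALSE)[, -1])
  }
  unflat <- function(m, d1, d2) {
    a <- array(0, c(d1, d2, S))
    for (s in seq_len(S)) a[, , s] <- matrix(m[s, ], d1, d2)
    a
  }
  theta <- get("theta"); Lambda <- get("Lambda"); eta <- get("eta")
  beta <- get("beta"); sigma2 <- get("sigma2"); gamma <- get("gamma")
  r <- ncol(beta) / k
  scalars <- readr::read_csv(file.path(dir, "scalars.csv"),
                             show_col_types = FALSE)
  basis <- basis_config(p, man$basis_locations, man$basis_bandwidth)
  structure(list(
    draws = list(
      theta = unflat(theta, n, p), Lambda = unflat(Lambda, p, k),
      eta = unflat(eta, n, k), beta = unflat(beta, r, k),
      sigma2 = t(sigma2), gamma = t(gamma),
      alpha = scalars$alpha, psi2 = scalars$psi2, loglik = scalars$loglik
    ),
    n_draws = S, basis = basis, k = k, ids = man$ids,
    z = NULL, age_center = man$age_center, age_scale = man$age_scale,
    y_center = man$y_center %||% 0, mcmc = man$mcmc
  ), class = "pp_fit")
}

config_hash <- function(x) {
  # dependency-free stable hash: sum of char codes of the serialized config
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 8)
  codes <- utf8ToInt(paste(s, collapse = ""))
  sprintf("%08x", sum(codes * seq_along(codes)) %% .Machine$integer.max)
}
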