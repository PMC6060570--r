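# Shared fixtures, all built in code at test time.

# Tiny hand-written results CSV: 2 athletes, 3 rows, one doped athlete.
write_toy_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "athlete_id,sex,birth_date,event_date,result_m,doped",
    "a1,male,1990-01-15,2012-03-01,18.20,0",
    "a1,male,1990-01-15,2012-03-11,18.55,0",
    "a2,female,1988-06-02,2012-04-01,17.10,1"
  ), path)
  path
}

# Small synthetic season used across tests; tiny cohorts get a larger
# doped fraction so the doped stratum is non-empty.
small_sim <- function(n = 30, seed = 1,
                      doped_fraction = if (n < 28) 0.1 else 0.0369, ...) {
  generate_dataset(sim_config(n_athletes = n, seed = seed,
                              doped_fraction = doped_fraction, ...))
}

# A quick fit on a small season (shared across test files via memoization).
quick_fit_cache <- new.env(parent = emptyenv())
quick_fit <- function() {
  if (is.null(quick_fit_cache$fit)) {
    sim <- small_sim(n = 40, seed = 7)
    quick_fit_cache$sim <- sim
    quick_fit_cache$fit <- fit_passport(
      sim$data, basis = sim$truth$basis, k = 2,
      iterations = 800, burnin = 300, thin = 2, seed = 11)
  }
  list(fit = quick_fit_cache$fit, sim = quick_fit_cache$sim)
}

# Toy conditioning values for single-block conditional checks
# (p = 3, k = 1, n = 5).
toy_state <- function(seed = 42) {
  set.seed(seed)
  n <- 5; p <- 3; k <- 1
  list(
    n = n, p = p, k = k,
    theta = matrix(rnorm(n * p), n, p),
    Lambda = matrix(c(0.8, -0.5, 0.3), p, k),
    eta = matrix(rnorm(n * k), n, k),
    sigma2 = c(0.5, 1.2, 0.8),
    psi2 = 0.25,
    beta = matrix(c(0.4, -0.2), 2, k),
    X = cbind(1, c(-1, -0.5, 0, 0.5, 1)),
    gamma = matrix(0.9, k, 1),
    alpha = -1.1,
    z = c(1L, 0L, 0L, 1L, 0L),
    u = c(0.5, -0.3, -1.2, 0.9, -0.1)
  )
}
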