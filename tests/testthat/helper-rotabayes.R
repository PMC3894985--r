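# Shared helpers: tiny record sets built in code, and independent oracles.

# a minimal complete field-year table (n rows, all cells populated)
toy_fields <- function(n = 3) {
  crops <- crop_vocabulary()
  tb <- tibble::tibble(
    field_id = sprintf("T%02d", seq_len(n)),
    year = 2000L + seq_len(n),
    species = rep(c("pima", "upland"), length.out = n),
    yield_kg_ha = 1400 + 10 * seq_len(n)
  )
  for (k in 1:10) tb[[paste0("prior_crop_", k)]] <- rep(crops[1 + (k %% 15)], n)
  for (cr in crops) tb[[paste0("adj_", cr)]] <- 0L
  tb$adj_cotton <- 4L
  tb$adj_wheat <- 2L
  tb
}

toy_lygus <- function(fields) {
  do.call(rbind, lapply(seq_len(nrow(fields)), function(i) {
    tibble::tibble(field_id = fields$field_id[i], year = fields$year[i],
                   day_of_year = c(150L, 160L, 170L, 185L),
                   density_per_sweep = c(0.2, 0.5, 0.4, 0.1))
  }))
}

toy_records <- function(n = 3) {
  f <- toy_fields(n)
  fy_records(f, toy_lygus(f))
}

# exhaustive minimal-width window search, kept deliberately loop-based and
# separate from hpdi()
hpdi_brute <- function(draws, mass = 0.95) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) {
      best <- c(s[i], s[i + m - 1])
    }
  }
  best
}

# closed-form Gaussian posterior of beta for the no-random-effects model
# with known residual variance (normal-equations route, no shared code)
beta_posterior_closed_form <- function(X, y, sigma2, beta_sd) {
  A <- t(X) %*% X / sigma2 + diag(ncol(X)) / beta_sd^2
  cov <- solve(A)
  list(mean = drop(cov %*% t(X) %*% y / sigma2), cov = cov)
}

fixture_records <- function() {
  read_records(
    system.file("extdata", "synthetic_records.csv", package = "rotabayes"),
    system.file("extdata", "synthetic_lygus.csv", package = "rotabayes"))
}

fast_mcmc <- function(seed = 1L) mcmc_config(n_chains = 3, n_iter = 800,
                                             n_burn = 400, seed = seed)
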