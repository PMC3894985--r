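test_that("beta full conditional matches the conjugate closed form", {
  # intercept-only, y = (1,1,1,1), sigma2 = 1: mean = 4 / (4 + 1e-4)
  d <- list(response = rep(1, 4), X = cbind("(Intercept)" = rep(1, 4)),
            field_index = NULL, year_index = NULL)
  fc <- beta_full_conditional(d, sigma2 = 1)
  expect_equal(unname(fc$mean), 4 / (4 + 1e-4), tolerance = 1e-12)
  expect_equal(fc$cov[1, 1], 1 / (4 + 1e-4), tolerance = 1e-12)

  # zero response -> zero mean, any design
  set.seed(3)
  X <- cbind(1, matrix(rnorm(20 * 2), 20))
  colnames(X) <- c("a", "b", "c")
  d0 <- list(response = rep(0, 20), X = X, field_index = NULL, year_index = NULL)
  expect_equal(unname(beta_full_conditional(d0, sigma2 = 2)$mean), rep(0, 3))

  # diffuse-prior limit reproduces ordinary least squares
  y <- rnorm(20, X %*% c(1, -2, 0.5), 0.3)
  dr <- list(response = y, X = X, field_index = NULL, year_index = NULL)
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  fc <- beta_full_conditional(dr, sigma2 = 0.09, prior = prior_spec(beta_sd = 1e8))
  expect_equal(unname(fc$mean), unname(ols), tolerance = 1e-6)

  # random effects shift the conditional through the adjusted response
  du <- list(response = y, X = X, field_index = rep(1:4, each = 5),
             year_index = NULL)
  u <- c(0.5, -0.5, 1, 0)
  fc_u <- beta_full_conditional(du, u = u, sigma2 = 1)
  manual <- solve(crossprod(X) + diag(3) / 1e4,
                  crossprod(X, y - u[rep(1:4, each = 5)]))
  expect_equal(unname(fc_u$mean), unname(drop(manual)), tolerance = 1e-10)
})

test_that("collinear designs are rejected with the offending columns named", {
  X <- cbind(ones = rep(1, 10), x = 1:10, x_copy = 1:10)
  d <- list(response = rnorm(10), X = X, field_index = NULL, year_index = NULL)
  expect_error(beta_full_conditional(d, sigma2 = 1e-12, prior = prior_spec(beta_sd = 1e12)),
               "collinear")
})

test_that("variance full conditional applies the conjugate update", {
  expect_equal(variance_full_conditional(c(1, -1)),
               c(shape = 1.001, scale = 1.001))
  expect_equal(variance_full_conditional(rep(0, 10)),
               c(shape = 5.001, scale = 0.001))
  x <- rnorm(25)
  a <- variance_full_conditional(x)
  b <- variance_full_conditional(2 * x)
  expect_equal(unname(b["scale"] - 0.001), unname(4 * (a["scale"] - 0.001)))
  expect_identical(unname(a["shape"]), unname(b["shape"]))
})

test_that("gibbs_fit is bit-reproducible given the master seed", {
  sim <- simulate_records(sim_config(n_fields = 15, years = 2001:2003,
                                     n_records = 40, master_seed = 2))
  d <- build_design(sim$records, 4, include_zero = TRUE)
  f1 <- gibbs_fit(d, config = mcmc_config(2, 200, 100, seed = 99))
  f2 <- gibbs_fit(d, config = mcmc_config(2, 200, 100, seed = 99))
  expect_identical(f1$chains, f2$chains)
  f3 <- gibbs_fit(d, config = mcmc_config(2, 200, 100, seed = 100))
  expect_false(identical(f1$chains[[1]]$beta, f3$chains[[1]]$beta))
})

test_that("variance draws are strictly positive and counts match the protocol", {
  sim <- simulate_records(sim_config(n_fields = 15, years = 2001:2003,
                                     n_records = 40, master_seed = 2))
  d <- build_design(sim$records, 1)
  f <- gibbs_fit(d, config = mcmc_config(3, 300, 120, seed = 4))
  for (ch in f$chains) {
    expect_identical(nrow(ch$beta), 180L)
    expect_true(all(ch$sigma2 > 0))
    expect_true(all(ch$sigma2_field > 0))
    expect_true(all(ch$sigma2_year > 0))
  }
})

test_that("with random effects off and sigma2 pinned the sampler matches the analytic posterior", {
  set.seed(10)
  X <- cbind("(Intercept)" = 1, x1 = rnorm(30), x2 = rnorm(30))
  y <- drop(X %*% c(2, 1, -1)) + rnorm(30, 0, 1.5)
  d <- list(response = y, X = X, field_index = NULL, year_index = NULL,
            field_levels = character(), year_levels = character(),
            dropped_columns = character(), model_id = NA)
  f <- gibbs_fit(d, config = mcmc_config(2, 2500, 0, seed = 8), fixed_sigma2 = 2.25)
  truth <- beta_posterior_closed_form(X, y, 2.25, 100)
  draws <- sapply(colnames(X), function(p) pooled_draws(f, p))
  mc_se <- sqrt(diag(truth$cov) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - truth$mean) < 3.5 * mc_se))
  expect_lt(norm(cov(draws) - truth$cov, "F") / norm(truth$cov, "F"), 0.1)
})

test_that("an identically-zero response gives effects centred at zero", {
  f0 <- toy_fields(12)
  f0$yield_kg_ha <- 1  # placeholder; replaced in the design below
  d <- build_design(fy_records(f0, toy_lygus(f0)), 1)
  d$response <- rep(0, length(d$response))
  f <- gibbs_fit(d, config = mcmc_config(2, 1500, 500, seed = 3))
  for (p in f$fixed_names) {
    dr <- pooled_draws(f, p)
    expect_lt(abs(mean(dr)), 4 * sd(dr) / sqrt(200))  # generous ESS allowance
  }
})

test_that("fits are invariant to input record order via the canonical sort", {
  sim <- simulate_records(sim_config(n_fields = 15, years = 2001:2003,
                                     n_records = 40, master_seed = 6))
  rec <- sim$records
  set.seed(1)
  shuffled <- fy_records(rec$fields[sample(nrow(rec$fields)), ], rec$lygus)
  d1 <- build_design(rec, 1)
  d2 <- build_design(shuffled, 1)
  expect_identical(d1$X, d2$X)
  expect_identical(gibbs_fit(d1, config = mcmc_config(2, 150, 50, seed = 5))$chains,
                   gibbs_fit(d2, config = mcmc_config(2, 150, 50, seed = 5))$chains)
})

test_that("rhat implements the classic between/within-chain formula", {
  # idealized separation: W = 1, B = 5000 -> sqrt(50.99)
  z <- as.vector(scale(rnorm(100)))  # mean exactly 0, sd exactly 1
  expect_equal(rhat(cbind(z, z + 10)), sqrt(50.99), tolerance = 1e-12)
  # exact copies with internal variation: B = 0 -> sqrt((n-1)/n)
  x <- rnorm(50)
  expect_equal(rhat(cbind(x, x)), sqrt(49 / 50), tolerance = 1e-12)
  # zero within-chain variance: undefined, not silently 1
  expect_true(is.na(rhat(cbind(rep(1, 10), rep(2, 10)))))
  # list input is accepted
  expect_equal(rhat(list(x, x)), sqrt(49 / 50), tolerance = 1e-12)
})

test_that("posterior means agree with an independent likelihood-based mixed-model fit", {
  skip_if_not_installed("lme4")
  sim <- simulate_records(sim_config(n_fields = 120, years = 2001:2006,
                                     n_records = 600, master_seed = 33))
  d <- build_design(sim$records, 4)
  f <- gibbs_fit(d, config = mcmc_config(3, 1500, 500, seed = 12))
  df <- data.frame(y = d$response, consec = d$X[, "consec_cotton"],
                   sp = d$X[, "species_upland"], adjc = d$X[, "adj_cotton"],
                   fld = factor(d$field_index), yr = factor(d$year_index))
  m <- lme4::lmer(y ~ consec + sp + adjc + (1 | fld) + (1 | yr), data = df)
  est <- summary(m)$coefficients
  for (pair in list(c("consec_cotton", "consec"), c("species_upland", "sp"),
                    c("adj_cotton", "adjc"))) {
    post <- mean(pooled_draws(f, pair[1]))
    expect_lt(abs(post - est[pair[2], "Estimate"]), 2 * est[pair[2], "Std. Error"])
  }
})

test_that("posterior draws serialize to columnar CSV with a JSON sidecar", {
  sim <- simulate_records(sim_config(n_fields = 10, years = 2001:2002,
                                     n_records = 18, master_seed = 4))
  d <- build_design(sim$records, 1)
  f <- gibbs_fit(d, config = mcmc_config(2, 100, 50, seed = 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_posterior(f, csv, js)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_identical(nrow(tab), 100L)  # 2 chains x 50 kept draws
  expect_true(all(c("chain", "iteration", "sigma2", "sigma2_field",
                    "sigma2_year", f$fixed_names) %in% names(tab)))
  side <- jsonlite::read_json(js)
  expect_named(side, c("prior", "config", "rhat", "floor_hits"))
})
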