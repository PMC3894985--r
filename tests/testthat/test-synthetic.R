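zero_effects <- function() setNames(rep(0, 14), setdiff(crop_vocabulary(), "cotton"))

test_that("the noiseless degenerate configuration is deterministic in the mean structure", {
  cfg <- sim_config(n_fields = 20, years = 2001:2004, n_records = 50,
                    sigma_field = 0, sigma_year = 0, sigma_resid = 0,
                    crop_yield_effects = zero_effects(),
                    crop_lygus_effects = zero_effects(),
                    consec_cotton_effect = 0, consec_lygus_effect = 0,
                    p_yield_missing = 0, sampling_noise_sd = 0,
                    seasonal_amplitude = 0, sigma_field_lygus = 0,
                    sigma_year_lygus = 0, master_seed = 9)
  sim <- simulate_records(cfg)
  f <- sim$records$fields
  expect_equal(f$yield_kg_ha,
               1500 + 160 * (f$species == "upland"))
  # constant latent trajectory with no observation noise: every sample and
  # the June mean equal the latent density
  expect_true(all(abs(sim$records$lygus$density_per_sweep - 0.5) < 1e-12))
  d2 <- build_design(sim$records, 2)
  expect_true(all(abs(d2$response - 0.5) < 1e-12))
})

test_that("missingness switches behave as probabilities", {
  cfg <- sim_config(n_fields = 20, years = 2001:2004, n_records = 60,
                    p_yield_missing = 1, p_adj_missing = 1, master_seed = 3)
  f <- simulate_records(cfg)$records$fields
  expect_true(all(is.na(f$yield_kg_ha)))
  expect_true(all(is.na(f$adj_cotton)))
})

test_that("the default configuration reproduces the source-database marginals", {
  sim <- simulate_records(sim_config(master_seed = 77))
  f <- sim$records$fields
  expect_identical(nrow(f), 1498L)
  expect_lte(length(unique(f$field_id)), 566L)
  expect_true(all(f$year %in% 1997:2008))
  # binomial tolerance (4 sd) around the expected observed counts
  expect_lt(abs(sum(!is.na(f$yield_kg_ha)) - 1240), 4 * sqrt(1498 * (1240 / 1498) * (258 / 1498)))
  expect_lt(abs(sum(!is.na(f$adj_cotton)) - 1026), 4 * sqrt(1498 * (1026 / 1498) * (472 / 1498)))
  hist_known <- rowSums(!is.na(as.matrix(f[paste0("prior_crop_", 1:4)])))
  expect_lt(abs(sum(hist_known == 4) - 782), 4 * sqrt(1498 * (782 / 1498) * (716 / 1498)))
  # everything the generator emits passes validation
  expect_identical(nrow(validate_records(sim$records)), 0L)
})

test_that("generation is byte-identical under a fixed master seed", {
  cfg <- sim_config(n_fields = 15, years = 2002:2004, n_records = 30, master_seed = 41)
  a <- simulate_records(cfg)
  b <- simulate_records(cfg)
  expect_identical(a$records$fields, b$records$fields)
  expect_identical(a$records$lygus, b$records$lygus)
  expect_identical(a$truth$u_field, b$truth$u_field)
  c2 <- simulate_records(sim_config(n_fields = 15, years = 2002:2004,
                                    n_records = 30, master_seed = 42))
  expect_false(identical(a$records$fields, c2$records$fields))
})

test_that("truth table labels align with the fitted contrast labels", {
  sim <- simulate_records(sim_config(n_fields = 20, years = 2001:2004,
                                     n_records = 60, master_seed = 13))
  tt <- truth_table(sim$truth)
  d <- build_design(sim$records, 1)
  f <- gibbs_fit(d, config = mcmc_config(2, 150, 50, seed = 1))
  ct <- crop_contrasts(f)
  expect_true(all(ct$label[ct$label != "cotton vs cotton"] %in%
                    tt$label[tt$model == 1]))
  expect_identical(tt$true_value[tt$model == 1 & tt$label == "tomatoes vs cotton"],
                   unname(default_crop_yield_effects()["tomatoes"]))
  expect_identical(tt$true_value[tt$model == 4], -40)
  # passthrough of a custom effect
  eff <- zero_effects(); eff["tomatoes"] <- 118
  sim2 <- simulate_records(sim_config(n_fields = 10, years = 2001:2002,
                                      n_records = 15, crop_yield_effects = eff,
                                      master_seed = 2))
  tt2 <- truth_table(sim2$truth)
  expect_identical(tt2$true_value[tt2$model == 1 & tt2$label == "tomatoes vs cotton"], 118)
})

test_that("effect_slope wires a known linear relation between the effect vectors", {
  cfg <- sim_config(n_fields = 10, years = 2001:2002, n_records = 15,
                    effect_slope = -300, effect_intercept = 20,
                    effect_noise_sd = 0, master_seed = 8)
  fitted <- coef(lm(cfg$crop_yield_effects ~ cfg$crop_lygus_effects))
  expect_equal(unname(fitted[2]), -300, tolerance = 1e-9)
  expect_equal(unname(fitted[1]), 20, tolerance = 1e-9)
  # and make_effect_pairs exposes the same hook for the stage-2 regression
  pairs <- make_effect_pairs(slope = -0.5, intercept = 1, noise_sd = 0)
  expect_equal(pairs$yield_effect, 1 - 0.5 * pairs$lygus_effect)
})

test_that("inconsistent configurations fail before any sampling", {
  expect_error(sim_config(n_fields = 2, years = 2001:2002, n_records = 10),
               "field-year pairs")
  expect_error(sim_config(p_yield_missing = 1.4), "probabilities")
  expect_error(sim_config(sigma_field = -1), "standard deviations")
  expect_error(sim_config(crop_freq = c(cotton = 1)), "15 crops")
})
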