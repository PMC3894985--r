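test_that("mean_density reproduces hand-computed trapezoid values", {
  w <- june_window(152, 162)
  # constant density over any days
  expect_equal(mean_density(c(150, 155, 163), c(0.7, 0.7, 0.7), w), 0.7)
  # linear ramp: mean is the midpoint
  expect_equal(mean_density(c(152, 162), c(0, 10), w), 5)
  # tent: areas (2+4)/2*5 + (4+0)/2*5 = 25 over 10 days
  expect_equal(mean_density(c(152, 157, 162), c(2, 4, 0), w), 2.5)
  # a single in-window sample returns its own density
  expect_equal(mean_density(160, 0.9, w), 0.9)
})

test_that("mean_density handles window coverage and boundary interpolation", {
  w <- june_window(152, 181)
  # no sample coverage of the window -> missing marker
  expect_true(is.na(mean_density(c(120, 140), c(1, 2), w)))
  expect_true(is.na(mean_density(c(190, 200), c(1, 2), w)))
  expect_true(is.na(mean_density(150, 3, w)))
  # samples straddling a boundary contribute via the interpolated boundary value:
  # ramp 0->30 over days 151..181 interpolates to 1 at day 152; mean over
  # [152,181] of a line from 1 to 30 is 15.5
  expect_equal(mean_density(c(151, 181), c(0, 30), w), 15.5)
  # result bounded by the contributing densities
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    day <- sort(sample(140:200, k))
    dens <- runif(k, 0, 3)
    m <- mean_density(day, dens, w)
    if (!is.na(m)) {
      expect_gte(m, min(dens) - 1e-12)
      expect_lte(m, max(dens) + 1e-12)
    }
  }
})

test_that("mean_density is invariant to interpolant-consistent points and input order", {
  w <- june_window(152, 181)
  set.seed(7)
  for (i in 1:25) {
    k <- sample(3:7, 1)
    day <- sort(sample(seq(145, 195, by = 2), k))
    dens <- runif(k, 0, 2)
    base <- mean_density(day, dens, w)
    # insert an extra sample lying exactly on the existing interpolant
    j <- sample(k - 1, 1)
    newday <- (day[j] + day[j + 1]) / 2
    newdens <- approx(day, dens, xout = newday)$y
    expect_equal(mean_density(c(day, newday), c(dens, newdens), w), base)
    # sample order does not matter
    o <- sample(k)
    expect_identical(mean_density(day[o], dens[o], w), base)
  }
})

test_that("consecutive_cotton matches the run-length definition on all 16 four-year histories", {
  for (bits in 0:15) {
    h <- ifelse(bitwAnd(bits, 2^(0:3)) > 0, "cotton", "wheat")
    expected <- 0L
    for (k in 1:4) {
      if (h[k] == "cotton") expected <- expected + 1L else break
    }
    expect_identical(consecutive_cotton(h), expected)
  }
  expect_identical(consecutive_cotton(c("cotton", "cotton", "wheat", "cotton")), 2L)
  expect_identical(consecutive_cotton(rep("cotton", 10)), 4L)  # capped at 4
})

test_that("consecutive_cotton marks incomplete 4-year histories ineligible", {
  expect_identical(consecutive_cotton(c("cotton", "cotton", "cotton")), NA_integer_)
  expect_identical(consecutive_cotton(c("cotton", NA, "cotton", "cotton")), NA_integer_)
  expect_identical(consecutive_cotton(character(0)), NA_integer_)
})

test_that("build_design uses cotton-reference one-hot coding", {
  f <- toy_fields(3)
  f$prior_crop_1 <- c("wheat", "cotton", "cotton")
  rec <- fy_records(f, toy_lygus(f))
  d <- build_design(rec, 1)
  expect_equal(unname(d$X[d$rows$field_id == "T01", "prior_wheat"]), 1)
  expect_equal(sum(d$X[, "prior_wheat"]), 1)
  # crops with no kept rows are dropped and reported
  expect_setequal(d$dropped_columns,
                  paste0("prior_", setdiff(crop_vocabulary(), c("cotton", "wheat"))))
  # species indicator: 1 = upland, 0 = pima
  expect_equal(unname(d$X[, "species_upland"]), as.numeric(f$species == "upland"))
})

test_that("build_design drop report reconciles with the input row count", {
  sim <- simulate_records(sim_config(n_fields = 30, years = 2002:2006,
                                     n_records = 90, master_seed = 5))
  for (m in c(1, 2, 4, 5)) {
    d <- build_design(sim$records, m)
    expect_identical(length(d$response) + sum(d$drop_report),
                     nrow(sim$records$fields))
    expect_false(anyNA(d$response))
    expect_false(anyNA(d$X))
    # grouping indices are dense
    expect_setequal(d$field_index, seq_along(d$field_levels))
    expect_setequal(d$year_index, seq_along(d$year_levels))
  }
  # direct count: force 3 missing yields in a 20-record set with complete data
  f <- toy_fields(20)
  f$prior_crop_1 <- "tomatoes"
  f$yield_kg_ha[c(2, 9, 17)] <- NA
  d <- build_design(fy_records(f, toy_lygus(f)), 1)
  expect_identical(length(d$response), 17L)
  expect_identical(unname(d$drop_report["missing_response"]), 3L)
})

test_that("build_design errors when no rows are eligible", {
  f <- toy_fields(4)
  f$prior_crop_1 <- "wheat"  # no cotton the year before anywhere
  rec <- fy_records(f, toy_lygus(f))
  expect_error(build_design(rec, 4), "no eligible rows")
  f$yield_kg_ha <- NA
  expect_error(build_design(fy_records(f, toy_lygus(f)), 1), "no eligible rows")
})

test_that("models 4/5 admit zero-consecutive records only when asked", {
  f <- toy_fields(6)
  f$prior_crop_1 <- c("cotton", "cotton", "wheat", "wheat", "cotton", "wheat")
  f$prior_crop_2 <- "cotton"
  rec <- fy_records(f, toy_lygus(f))
  d_strict <- build_design(rec, 4)
  expect_identical(length(d_strict$response), 3L)
  expect_identical(unname(d_strict$drop_report["zero_consecutive_cotton"]), 3L)
  d_zero <- build_design(rec, 4, include_zero = TRUE)
  expect_identical(length(d_zero$response), 6L)
  expect_setequal(d_zero$X[, "consec_cotton"], c(0, 2))
})
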