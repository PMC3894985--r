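#' Default per-crop effects and rotation frequencies for the generator
#'
#' Fixed, named default vectors for the synthetic-data generator: the
#' prior-year effect of each non-cotton crop on lint yield (kg/ha,
#' relative to cotton) and on mean June Lygus density (insects/sweep,
#' relative to cotton), and the landscape crop-frequency vector used for
#' rotation histories and adjacent fields. The effect defaults are set to
#' the order of magnitude reported for this system -- yield effects of
#' tens to hundreds of kg/ha, Lygus effects under one insect per sweep,
#' negatively related overall, with garlic as the known exception
#' (positive on both) -- and cotton dominates the crop frequencies, as it
#' does in a cotton-growing landscape.
#'
#' @return Named numeric vector (14 crops for the effects, 15 for the
#'   frequencies, which sum to 1).
#' @export
default_crop_yield_effects <- function() {
  c(alfalfa = -80, barley = 10, carrots = 20, corn = -60, garbanzo = 0,
    garlic = 128, lettuce = 30, melons = 440, onions = -40, potatoes = 15,
    safflower = -110, sugarbeets = -100, tomatoes = 118, wheat = 40)
}

#' @rdname default_crop_yield_effects
#' @export
default_crop_lygus_effects <- function() {
  c(alfalfa = 0.45, barley = 0.05, carrots = 0, corn = 0.70, garbanzo = 0.10,
    garlic = 0.28, lettuce = -0.05, melons = -0.15, onions = 0.40,
    potatoes = 0.05, safflower = 0.45, sugarbeets = 0.35, tomatoes = -0.20,
    wheat = 0.08)
}

#' @rdname default_crop_yield_effects
#' @export
default_crop_frequencies <- function() {
  c(alfalfa = 0.05, barley = 0.02, carrots = 0.02, corn = 0.04, cotton = 0.55,
    garbanzo = 0.01, garlic = 0.02, lettuce = 0.02, melons = 0.02,
    onions = 0.02, potatoes = 0.02, safflower = 0.03, sugarbeets = 0.02,
    tomatoes = 0.07, wheat = 0.09)
}

#' Configuration of the synthetic record generator
#'
#' Describes the generative model the analysis assumes, with known ground
#' truth: crossed field/year Gaussian effects on yield and on latent June
#' Lygus density, per-prior-crop effects relative to cotton, a
#' consecutive-cotton penalty, adjacency counts drawn from a landscape
#' crop-frequency vector, weekly June--July sweep samples around a
#' piecewise-linear seasonal trajectory, and yield/adjacency missingness.
#' The default marginals mirror the source database: 1498 field-year
#' records from 566 fields over 1997--2008, yield observed for 1240/1498,
#' adjacency for 1026/1498, and a complete 4-year rotation record for
#' 782/1498.
#'
#' @param n_fields Number of distinct fields.
#' @param years Vector of calendar years records may fall in.
#' @param n_records Number of field-year records (unique pairs).
#' @param base_yield Mean Pima lint yield, kg/ha.
#' @param species_effect Upland minus Pima yield difference, kg/ha.
#' @param p_upland Probability a field grows upland cotton.
#' @param sigma_field,sigma_year,sigma_resid SDs of the field effect, year
#'   effect and residual on yield, kg/ha.
#' @param crop_yield_effects,crop_lygus_effects Named length-14 vectors of
#'   prior-crop effects relative to cotton (kg/ha; insects/sweep).
#' @param effect_slope,effect_intercept,effect_noise_sd If `effect_slope`
#'   is non-`NULL`, `crop_yield_effects` is regenerated as
#'   `effect_intercept + effect_slope * crop_lygus_effects + noise`,
#'   wiring a known linear relation between the two effect vectors (the
#'   hook that makes the second-stage regression testable end to end).
#' @param consec_cotton_effect Yield change per consecutive prior cotton
#'   year, kg/ha.
#' @param consec_lygus_effect June Lygus change per consecutive prior
#'   cotton year, insects/sweep.
#' @param lygus_base Latent June Lygus density after cotton, insects/sweep.
#' @param sigma_field_lygus,sigma_year_lygus SDs of the field and year
#'   effects on latent June Lygus density.
#' @param crop_freq Named length-15 landscape crop-frequency vector.
#' @param rotation_transition Probability a field repeats the previous
#'   year's crop rather than redrawing from `crop_freq`.
#' @param p_complete_history Probability a record's rotation history is
#'   known for at least the previous 4 years (4--10 known entries);
#'   otherwise 1--3 entries are known.
#' @param adj_yield_effects,adj_lygus_effects Optional named length-15
#'   per-adjacent-field nuisance effects; default all zero.
#' @param adj_focal_corr Probability each adjacent field simply copies the
#'   focal field's prior crop (spatial confounding knob), default 0.
#' @param p_yield_missing,p_adj_missing Missingness probabilities for
#'   yield and for the adjacency block as a whole.
#' @param sampling_start_day,sampling_end_day,sampling_interval Sweep
#'   sampling span (day of year) and cadence in days.
#' @param seasonal_amplitude Relative amplitude of the within-season tent
#'   in the latent density trajectory; 0 gives a constant trajectory.
#' @param sampling_noise_sd SD of the truncated-at-zero Normal observation
#'   noise on sweep densities.
#' @param noise_model `"truncnorm"` (matches the Gaussian fitting
#'   assumptions) or `"poisson"` (counts over 50 sweeps, for robustness
#'   experiments).
#' @param master_seed Seed; identical configs generate byte-identical
#'   records.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_fields = 566L,
                       years = 1997:2008,
                       n_records = 1498L,
                       base_yield = 1500,
                       species_effect = 160,
                       p_upland = 0.6,
                       sigma_field = 150,
                       sigma_year = 100,
                       sigma_resid = 200,
                       crop_yield_effects = default_crop_yield_effects(),
                       crop_lygus_effects = default_crop_lygus_effects(),
                       effect_slope = NULL,
                       effect_intercept = 0,
                       effect_noise_sd = 0,
                       consec_cotton_effect = -40,
                       consec_lygus_effect = 0.037,
                       lygus_base = 0.5,
                       sigma_field_lygus = 0.15,
                       sigma_year_lygus = 0.10,
                       crop_freq = default_crop_frequencies(),
                       rotation_transition = 0.5,
                       p_complete_history = 782 / 1498,
                       adj_yield_effects = NULL,
                       adj_lygus_effects = NULL,
                       adj_focal_corr = 0,
                       p_yield_missing = 258 / 1498,
                       p_adj_missing = 472 / 1498,
                       sampling_start_day = 152L,
                       sampling_end_day = 212L,
                       sampling_interval = 7L,
                       seasonal_amplitude = 0.3,
                       sampling_noise_sd = 0.08,
                       noise_model = c("truncnorm", "poisson"),
                       master_seed = 20140117L) {
  noise_model <- match.arg(noise_model)
  noncotton <- setdiff(crop_vocabulary(), "cotton")
  if (is.null(adj_yield_effects)) adj_yield_effects <- setNames(rep(0, 15), crop_vocabulary())
  if (is.null(adj_lygus_effects)) adj_lygus_effects <- setNames(rep(0, 15), crop_vocabulary())

  args <- mget(setdiff(names(formals(sim_config)), c("effect_slope",
               "effect_intercept", "effect_noise_sd")))
  cfg <- structure(args, class = "sim_config")

  if (!setequal(names(crop_yield_effects), noncotton) ||
      !setequal(names(crop_lygus_effects), noncotton)) {
    stop("crop effect vectors must be named by the 14 non-cotton crops")
  }
  if (!setequal(names(crop_freq), crop_vocabulary()) ||
      abs(sum(crop_freq) - 1) > 1e-8 || any(crop_freq < 0)) {
    stop("crop_freq must be a probability vector over the 15 crops")
  }
  probs <- c(p_upland, rotation_transition, p_complete_history, adj_focal_corr,
             p_yield_missing, p_adj_missing)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  sds <- c(sigma_field, sigma_year, sigma_resid, sigma_field_lygus,
           sigma_year_lygus, sampling_noise_sd, effect_noise_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (n_records > n_fields * length(years)) {
    stop("n_records exceeds the number of distinct field-year pairs")
  }
  if (sampling_start_day >= sampling_end_day) stop("bad sampling span")

  if (!is.null(effect_slope)) {
    set.seed(master_seed)
    cfg$crop_yield_effects <- setNames(
      effect_intercept + effect_slope * crop_lygus_effects[noncotton] +
        rnorm(length(noncotton), 0, effect_noise_sd),
      noncotton)
  }
  cfg$crop_yield_effects <- cfg$crop_yield_effects[noncotton]
  cfg$crop_lygus_effects <- cfg$crop_lygus_effects[noncotton]
  cfg
}

# draw from a Normal truncated at zero (lower bound); sd 0 returns the mean
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(pmax(mean, 0))
  p0 <- pnorm(0, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

#' Generate a synthetic record set with known ground truth
#'
#' Draws field-year records from the generative counterpart of the fitted
#' models: each record gets a rotation history from a repeat-or-redraw
#' Markov chain over the 15 crops; field and year effects are Gaussian
#' with the configured SDs; the latent June Lygus mean is baseline +
#' prior-crop effect + consecutive-cotton term + field/year perturbations,
#' observed through weekly noisy sweep samples around a piecewise-linear
#' seasonal trajectory; yield is base + species + prior-crop effect +
#' consecutive-cotton penalty + adjacency nuisance terms + field/year
#' effects + residual noise; and yield/adjacency are masked at the
#' configured missingness rates. Deterministic given `master_seed`.
#'
#' @param config A [sim_config()].
#' @return List with `records` (an [fy_records] object that always passes
#'   [validate_records()]) and `truth` (class `sim_truth`: the realized
#'   field/year effects, all effect parameters, and the per-record latent
#'   state, keyed to match the fitted models' labels).
#' @export
simulate_records <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$master_seed)
  crops <- crop_vocabulary()
  noncotton <- setdiff(crops, "cotton")

  field_ids <- sprintf("F%04d", seq_len(cfg$n_fields))
  field_species <- ifelse(runif(cfg$n_fields) < cfg$p_upland, "upland", "pima")
  names(field_species) <- field_ids

  grid <- expand.grid(field = field_ids, year = cfg$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pick <- sort(sample.int(nrow(grid), cfg$n_records))
  rec_field <- grid$field[pick]
  rec_year <- as.integer(grid$year[pick])
  n <- cfg$n_records

  # rotation histories: repeat-or-redraw chain, known depth 1-3 or 4-10
  hist_len <- ifelse(runif(n) < cfg$p_complete_history,
                     sample(4:10, n, replace = TRUE),
                     sample(1:3, n, replace = TRUE))
  histories <- matrix(NA_character_, n, 10)
  for (i in seq_len(n)) {
    h <- character(hist_len[i])
    h[1] <- sample(crops, 1, prob = cfg$crop_freq)
    if (hist_len[i] > 1) {
      for (k in 2:hist_len[i]) {
        h[k] <- if (runif(1) < cfg$rotation_transition) h[k - 1]
                else sample(crops, 1, prob = cfg$crop_freq)
      }
    }
    histories[i, seq_len(hist_len[i])] <- h
  }

  # realized consecutive-cotton run over the known history, capped at 4
  consec_real <- apply(histories, 1, function(h) {
    h <- h[!is.na(h)]
    run <- 0L
    for (k in seq_len(min(4, length(h)))) {
      if (h[k] == "cotton") run <- run + 1L else break
    }
    run
  })

  u_field <- setNames(rnorm(cfg$n_fields, 0, cfg$sigma_field), field_ids)
  v_year <- setNames(rnorm(length(cfg$years), 0, cfg$sigma_year),
                     as.character(cfg$years))
  u_field_lygus <- setNames(rnorm(cfg$n_fields, 0, cfg$sigma_field_lygus), field_ids)
  v_year_lygus <- setNames(rnorm(length(cfg$years), 0, cfg$sigma_year_lygus),
                           as.character(cfg$years))

  # 8 adjacent fields per record
  adj_counts <- matrix(0L, n, 15, dimnames = list(NULL, crops))
  for (i in seq_len(n)) {
    nb <- sample(crops, 8, replace = TRUE, prob = cfg$crop_freq)
    if (cfg$adj_focal_corr > 0) {
      copy <- runif(8) < cfg$adj_focal_corr
      nb[copy] <- histories[i, 1]
    }
    adj_counts[i, ] <- tabulate(match(nb, crops), nbins = 15)
  }

  crop_eff <- function(tab) {
    e <- rep(0, n)
    idx <- histories[, 1] %in% noncotton
    e[idx] <- tab[histories[idx, 1]]
    e
  }

  species <- field_species[rec_field]
  yield_mean <- cfg$base_yield +
    cfg$species_effect * (species == "upland") +
    crop_eff(cfg$crop_yield_effects) +
    cfg$consec_cotton_effect * consec_real +
    drop(adj_counts %*% cfg$adj_yield_effects[crops]) +
    u_field[rec_field] + v_year[as.character(rec_year)]
  yield_obs <- pmax(yield_mean + rnorm(n, 0, cfg$sigma_resid), 1)

  lygus_mean <- pmax(
    cfg$lygus_base +
      crop_eff(cfg$crop_lygus_effects) +
      cfg$consec_lygus_effect * consec_real +
      drop(adj_counts %*% cfg$adj_lygus_effects[crops]) +
      u_field_lygus[rec_field] + v_year_lygus[as.character(rec_year)],
    0.02)

  # seasonal tent, unit mean over the June window
  peak <- (cfg$sampling_start_day + cfg$sampling_end_day) / 2
  tent <- function(t) pmax(0, 1 - abs(t - peak) / 40)
  jw <- june_window()
  rbar <- mean(tent(seq(jw$start_day, jw$end_day)))
  shape <- function(t) 1 + cfg$seasonal_amplitude * (tent(t) - rbar)

  samp <- vector("list", n)
  offsets <- sample(0:6, n, replace = TRUE)
  for (i in seq_len(n)) {
    days <- seq(cfg$sampling_start_day + offsets[i], cfg$sampling_end_day,
                by = cfg$sampling_interval)
    traj <- lygus_mean[i] * shape(days)
    dens <- if (cfg$noise_model == "truncnorm") {
      rtnorm0(length(days), traj, cfg$sampling_noise_sd)
    } else {
      stats::rpois(length(days), 50 * traj) / 50
    }
    samp[[i]] <- tibble::tibble(field_id = rec_field[i], year = rec_year[i],
                                day_of_year = as.integer(days),
                                density_per_sweep = dens)
  }
  lygus_tab <- do.call(rbind, samp)

  # missingness masks
  yield_obs[runif(n) < cfg$p_yield_missing] <- NA_real_
  adj_out <- adj_counts
  adj_out[runif(n) < cfg$p_adj_missing, ] <- NA_integer_

  fields_tab <- tibble::tibble(field_id = rec_field, year = rec_year,
                               species = unname(species),
                               yield_kg_ha = yield_obs)
  for (k in 1:10) fields_tab[[paste0("prior_crop_", k)]] <- histories[, k]
  for (cr in crops) fields_tab[[paste0("adj_", cr)]] <- as.integer(adj_out[, cr])

  records <- fy_records(fields_tab, lygus_tab)
  truth <- structure(list(
    config = cfg,
    crop_yield_effects = cfg$crop_yield_effects,
    crop_lygus_effects = cfg$crop_lygus_effects,
    species_effect = cfg$species_effect,
    consec_cotton_effect = cfg$consec_cotton_effect,
    consec_lygus_effect = cfg$consec_lygus_effect,
    base_yield = cfg$base_yield,
    lygus_base = cfg$lygus_base,
    u_field = u_field, v_year = v_year,
    u_field_lygus = u_field_lygus, v_year_lygus = v_year_lygus,
    records = tibble::tibble(field_id = rec_field, year = rec_year,
                             prior_crop = histories[, 1],
                             consec_cotton = consec_real,
                             latent_june_mean = lygus_mean,
                             expected_yield = yield_mean)
  ), class = "sim_truth")
  list(records = records, truth = truth)
}

#' Ground-truth effect table
#'
#' Aligns each fitted-model contrast label with its true generative value,
#' for recovery scoring: one row per non-cotton crop for the yield
#' (Model 1) and Lygus (Model 2) contrasts, the species contrast for
#' both responses, and the consecutive-cotton slopes (Models 4/5).
#'
#' @param truth The `truth` component of [simulate_records()].
#' @return Tibble with columns `model`, `label`, `true_value`.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  noncotton <- names(truth$crop_yield_effects)
  rbind(
    tibble::tibble(model = 1L, label = paste(noncotton, "vs cotton"),
                   true_value = unname(truth$crop_yield_effects)),
    tibble::tibble(model = 1L, label = "upland vs pima",
                   true_value = truth$species_effect),
    tibble::tibble(model = 2L, label = paste(noncotton, "vs cotton"),
                   true_value = unname(truth$crop_lygus_effects)),
    tibble::tibble(model = 4L, label = "per consecutive cotton year",
                   true_value = truth$consec_cotton_effect),
    tibble::tibble(model = 5L, label = "per consecutive cotton year",
                   true_value = truth$consec_lygus_effect)
  )
}

#' Build effect pairs with a known linear relation
#'
#' Constructs a 14-crop effect-pair table in which the yield effects are
#' an exact (or noisy) linear function of the Lygus effects:
#' `yield = intercept + slope * lygus + Normal(0, noise_sd)`. Used to
#' exercise the second-stage regression with known truth.
#'
#' @param slope,intercept True linear coefficients.
#' @param noise_sd SD of the added scatter.
#' @param lygus_effects Named length-14 Lygus effect vector.
#' @param seed RNG seed for the scatter.
#' @return Tibble with `crop`, `yield_effect`, `lygus_effect`.
#' @export
make_effect_pairs <- function(slope, intercept = 0, noise_sd = 0,
                              lygus_effects = default_crop_lygus_effects(),
                              seed = 1L) {
  set.seed(seed)
  tibble::tibble(
    crop = names(lygus_effects),
    lygus_effect = unname(lygus_effects),
    yield_effect = intercept + slope * unname(lygus_effects) +
      rnorm(length(lygus_effects), 0, noise_sd)
  )
}
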