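#' Pair the crop effects on yield with the crop effects on Lygus
#'
#' Joins the Model-1 (yield) and Model-2 (June Lygus) posterior-mean
#' contrasts against cotton into one table of effect pairs, one row per
#' non-cotton crop available in both fits.
#'
#' @param yield_contrasts,lygus_contrasts [crop_contrasts()] tables from
#'   the Model-1 and Model-2 fits.
#' @return Tibble with columns `crop`, `yield_effect` (kg/ha) and
#'   `lygus_effect` (insects/sweep).
#' @export
effect_pairs <- function(yield_contrasts, lygus_contrasts) {
  keep <- function(tb) {
    tb <- tb[tb$available & grepl(" vs cotton$", tb$label) &
               tb$label != "cotton vs cotton", ]
    tibble::tibble(crop = sub(" vs cotton$", "", tb$label),
                   post_mean = tb$post_mean)
  }
  a <- keep(yield_contrasts)
  b <- keep(lygus_contrasts)
  common <- intersect(a$crop, b$crop)
  tibble::tibble(
    crop = common,
    yield_effect = a$post_mean[match(common, a$crop)],
    lygus_effect = b$post_mean[match(common, b$crop)]
  )
}

#' Regress crop yield effects on crop Lygus effects
#'
#' The second-stage ("Model 3") regression: a Bayesian simple linear
#' regression of the posterior-mean yield contrasts on the posterior-mean
#' Lygus contrasts across the non-cotton crops, with Normal(0,
#' `beta_sd`^2) priors on intercept and slope and an inverse-gamma prior
#' on the residual variance. Implemented as the degenerate mixed model
#' with no random-effect groups, so it reuses the same Gibbs machinery as
#' the field-level fits.
#'
#' By construction this propagates only the point estimates (posterior
#' means) from the first-stage fits, ignoring their uncertainty; see the
#' methods vignette for a sensitivity mode that pairs random first-stage
#' draws instead.
#'
#' @param pairs An [effect_pairs()] table (or any tibble with
#'   `yield_effect` and `lygus_effect`), at least 3 rows with
#'   non-identical `lygus_effect` values.
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @return List with `fit` (the [gibbs_fit()] object), `slope` and
#'   `intercept` ([summarize_effect()] rows), and `pairs`.
#' @export
fit_effect_regression <- function(pairs, prior = prior_spec(),
                                  config = mcmc_config()) {
  stopifnot(nrow(pairs) >= 3)
  x <- pairs$lygus_effect
  y <- pairs$yield_effect
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  if (length(unique(x)) < 2) {
    stop("slope unidentifiable: all lygus_effect values are equal")
  }
  design <- list(
    response = y,
    X = cbind("(Intercept)" = 1, slope = x),
    fixed_names = c("(Intercept)", "slope"),
    field_index = NULL, year_index = NULL,
    field_levels = character(), year_levels = character(),
    dropped_columns = character(), model_id = 3L
  )
  fit <- gibbs_fit(design, prior, config)
  list(
    fit = fit,
    slope = summarize_effect(pooled_draws(fit, "slope"), "lygus effect slope"),
    intercept = summarize_effect(pooled_draws(fit, "(Intercept)"), "intercept"),
    pairs = pairs
  )
}

#' Draw-paired sensitivity variant of the effect regression
#'
#' Instead of regressing posterior means, pairs random first-stage draws:
#' for each of `n_draws` repetitions one posterior draw per crop is taken
#' from each first-stage fit, the ordinary least-squares slope of the
#' resulting 14-point cloud is recorded, and the distribution of those
#' slopes is summarized. This propagates first-stage uncertainty the
#' point-estimate regression ignores.
#'
#' @param yield_fit,lygus_fit [gibbs_fit()] results for Models 1 and 2.
#' @param n_draws Number of paired draws.
#' @param seed RNG seed for the pairing.
#' @return List with `slope_draws` and `slope` (summary row).
#' @export
effect_regression_draws <- function(yield_fit, lygus_fit, n_draws = 2000,
                                    seed = 1L) {
  crops <- intersect(
    grep("^prior_", yield_fit$fixed_names, value = TRUE),
    grep("^prior_", lygus_fit$fixed_names, value = TRUE))
  stopifnot(length(crops) >= 3)
  ydraws <- vapply(crops, function(cc) pooled_draws(yield_fit, cc),
                   numeric(length(pooled_draws(yield_fit, crops[1]))))
  ldraws <- vapply(crops, function(cc) pooled_draws(lygus_fit, cc),
                   numeric(length(pooled_draws(lygus_fit, crops[1]))))
  set.seed(seed)
  iy <- sample.int(nrow(ydraws), n_draws, replace = TRUE)
  il <- sample.int(nrow(ldraws), n_draws, replace = TRUE)
  slopes <- vapply(seq_len(n_draws), function(t) {
    xx <- ldraws[il[t], ]
    yy <- ydraws[iy[t], ]
    sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  }, numeric(1))
  list(slope_draws = slopes,
       slope = summarize_effect(slopes, "lygus effect slope (draw-paired)"))
}
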