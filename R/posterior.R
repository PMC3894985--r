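#' Highest posterior density interval
#'
#' The narrowest region of parameter space containing the stated posterior
#' mass: draws are sorted and, over all contiguous windows of
#' `m = ceiling(mass * n)` draws, the one of minimal width is returned
#' (leftmost window on ties). `mass = 1` gives the sample range exactly.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass in (0, 1]; default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(c(0, 1, 2, 3, 100), mass = 0.8)  # c(0, 3)
#' @export
hpdi <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass > 1) {
    stop("mass must be a single probability in (0, 1]")
  }
  n <- length(draws)
  m <- ceiling(mass * n)
  if (m < 2) stop("need at least 2 draws inside the interval (have ", n, ")")
  s <- sort(draws)
  if (m == n) return(c(lower = s[1], upper = s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)  # which.min takes the first minimum: leftmost window
  c(lower = s[i], upper = s[i + m - 1])
}

#' Posterior sign probability
#'
#' Fraction of draws strictly below zero -- the reporting device for "the
#' posterior probability of a negative effect". Draws exactly at zero
#' count as non-negative, so `sign_probability(x) + mean(x >= 0)` is
#' exactly 1.
#'
#' @param draws Numeric vector of posterior draws (at least one).
#' @return Probability in \[0, 1\].
#' @export
sign_probability <- function(draws) {
  stopifnot(length(draws) >= 1)
  mean(draws < 0)
}

#' Summarize one effect's pooled draws
#'
#' @param draws Pooled posterior draws for one effect.
#' @param label Effect name.
#' @param mass HPDI mass.
#' @return One-row tibble: `label`, `post_mean`, `hpdi_low`, `hpdi_high`,
#'   `prob_negative`, `flagged` (HPDI excludes 0), `available`.
#' @export
summarize_effect <- function(draws, label, mass = 0.95) {
  h <- hpdi(draws, mass)
  tibble::tibble(
    label = label,
    post_mean = mean(draws),
    hpdi_low = h[["lower"]],
    hpdi_high = h[["upper"]],
    prob_negative = sign_probability(draws),
    flagged = h[["lower"]] > 0 || h[["upper"]] < 0,
    available = TRUE
  )
}

#' Prior-crop contrasts against the cotton baseline
#'
#' One summary per non-cotton prior crop (the design codes cotton as the
#' reference, so each crop coefficient *is* the contrast against cotton),
#' plus the species contrast (upland minus Pima). Draws are pooled across
#' chains before summarizing. The implied cotton-vs-cotton contrast is
#' included as an exact zero reference row; crops whose indicator column
#' was dropped from the design (no records) are returned as unavailable.
#'
#' @param fit A [gibbs_fit()] result for Model 1 or 2.
#' @param mass HPDI mass.
#' @return Tibble of contrast summaries, one row per crop plus species.
#' @export
crop_contrasts <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "posterior_samples"))
  rows <- list(tibble::tibble(
    label = "cotton vs cotton", post_mean = 0, hpdi_low = 0, hpdi_high = 0,
    prob_negative = 0, flagged = FALSE, available = TRUE))
  for (cr in setdiff(crop_vocabulary(), "cotton")) {
    col <- paste0("prior_", cr)
    lab <- paste(cr, "vs cotton")
    if (col %in% fit$fixed_names) {
      rows[[length(rows) + 1]] <- summarize_effect(pooled_draws(fit, col), lab, mass)
    } else {
      rows[[length(rows) + 1]] <- tibble::tibble(
        label = lab, post_mean = NA_real_, hpdi_low = NA_real_,
        hpdi_high = NA_real_, prob_negative = NA_real_, flagged = NA,
        available = FALSE)
    }
  }
  if ("species_upland" %in% fit$fixed_names) {
    rows[[length(rows) + 1]] <- summarize_effect(
      pooled_draws(fit, "species_upland"), "upland vs pima", mass)
  }
  do.call(rbind, rows)
}

#' Consecutive-cotton slope summary
#'
#' Summary of the per-year yield (or Lygus) change for each additional
#' consecutive prior cotton planting, plus the species contrast, from a
#' Model 4/5 fit.
#'
#' @param fit A [gibbs_fit()] result for Model 4 or 5.
#' @param mass HPDI mass.
#' @return Tibble with the slope row (`"per consecutive cotton year"`)
#'   and the species row.
#' @export
consec_contrasts <- function(fit, mass = 0.95) {
  stopifnot("consec_cotton" %in% fit$fixed_names)
  rbind(
    summarize_effect(pooled_draws(fit, "consec_cotton"),
                     "per consecutive cotton year", mass),
    summarize_effect(pooled_draws(fit, "species_upland"), "upland vs pima", mass)
  )
}

#' Convert an absolute yield slope to percent change per year
#'
#' Divides each slope draw (kg/ha per consecutive cotton year) by a
#' baseline yield and scales to percent. The recommended baseline is the
#' mean observed yield among the records entering the consecutive-cotton
#' model, the only denominator computable from the model's own data.
#'
#' @param slope_draws Posterior draws of the slope (kg/ha per year).
#' @param baseline Baseline yield in kg/ha (> 0).
#' @param mass HPDI mass for the summary.
#' @return List with `draws` (percent-per-year draws) and `summary` (a
#'   [summarize_effect()] row labelled `"percent change per year"`).
#' @export
percent_change <- function(slope_draws, baseline, mass = 0.95) {
  if (!is.numeric(baseline) || length(baseline) != 1 || baseline <= 0) {
    stop("baseline must be a single positive yield (kg/ha)")
  }
  pct <- slope_draws * 100 / baseline
  list(draws = pct,
       summary = summarize_effect(pct, "percent change per year", mass))
}
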