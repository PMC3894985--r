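#' Run one model of the analysis end to end
#'
#' Orchestrates one of the five analysis stages on a record set: builds
#' the design ([build_design()]), fits by Gibbs sampling ([gibbs_fit()] or
#' [fit_effect_regression()]), summarizes the posterior the way results
#' are reported (contrasts against cotton, 95% HPDIs, sign
#' probabilities), and optionally writes the contrast table, convergence
#' table, drop report and a config echo to `out_dir`. Model 3 regresses
#' the Model-1 posterior-mean contrasts on the Model-2 ones; pass
#' previously computed fits via `fits = list(m1 = ..., m2 = ...)` (each a
#' [run_model()] bundle) or they are computed on the fly.
#'
#' Record attrition is logged in the drop report so input rows always
#' reconcile: rows kept + rows dropped = rows in. A warning is raised if
#' any reported effect parameter has an R-hat of 1.1 or more.
#'
#' @param model_id One of 1, 2, 3, 4, 5.
#' @param records An [fy_records] object (ignored for Model 3 when `fits`
#'   is supplied).
#' @param prior A [prior_spec()].
#' @param mcmc An [mcmc_config()].
#' @param window [june_window()] for the Lygus response.
#' @param include_zero Admit zero consecutive-cotton records (Models 4/5).
#' @param pc_baseline Optional baseline yield (kg/ha) for the
#'   percent-change conversion; default is the mean observed yield among
#'   the rows entering Model 4.
#' @param fits For Model 3: list with elements `m1` and `m2`.
#' @param out_dir Optional output directory.
#' @return A report bundle (list): `model_id`, `design`, `fit`,
#'   `contrasts` (or `slope`/`pairs` for Model 3), `rhat`, `drop_report`,
#'   `converged`, and for Model 4 also `percent_change`.
#' @export
run_model <- function(model_id, records = NULL, prior = prior_spec(),
                      mcmc = mcmc_config(), window = june_window(),
                      include_zero = FALSE, pc_baseline = NULL,
                      fits = NULL, out_dir = NULL) {
  stopifnot(model_id %in% 1:5)

  if (model_id == 3) {
    if (is.null(fits)) {
      if (is.null(records)) stop("model 3 needs `records` or `fits`")
      fits <- list(m1 = run_model(1, records, prior, mcmc, window),
                   m2 = run_model(2, records, prior, mcmc, window))
    }
    if (is.null(fits$m1) || is.null(fits$m2)) {
      stop("model 3 requires the Model 1 and Model 2 outputs (fits$m1, fits$m2)")
    }
    pairs <- effect_pairs(fits$m1$contrasts, fits$m2$contrasts)
    reg <- fit_effect_regression(pairs, prior, mcmc)
    rh <- rhat_table(reg$fit)
    bundle <- list(model_id = 3L, design = NULL, fit = reg$fit,
                   slope = reg$slope, intercept = reg$intercept,
                   pairs = pairs, rhat = rh,
                   drop_report = integer(0),
                   converged = all(rh$rhat < 1.1, na.rm = TRUE))
    if (!bundle$converged) warning("model 3: R-hat >= 1.1 for some parameter")
    if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
    return(bundle)
  }

  stopifnot(inherits(records, "fy_records"))
  design <- build_design(records, model_id, window, include_zero)
  fit <- gibbs_fit(design, prior, mcmc)
  contrasts <- if (model_id %in% c(1, 2)) crop_contrasts(fit) else consec_contrasts(fit)
  rh <- rhat_table(fit)

  # convergence gate on the inferential targets (the reported effects)
  reported <- intersect(
    c(grep("^prior_", fit$fixed_names, value = TRUE),
      "species_upland", "consec_cotton"),
    fit$fixed_names)
  rh_rep <- rh$rhat[rh$parameter %in% reported]
  converged <- all(rh_rep < 1.1, na.rm = TRUE) && !anyNA(rh_rep)
  bundle <- list(model_id = as.integer(model_id), design = design, fit = fit,
                 contrasts = contrasts, rhat = rh,
                 drop_report = design$drop_report, converged = converged)

  if (model_id == 4) {
    baseline <- if (is.null(pc_baseline)) mean(design$response) else pc_baseline
    bundle$percent_change <- percent_change(
      pooled_draws(fit, "consec_cotton"), baseline)
    bundle$pc_baseline <- baseline
  }
  if (!converged) {
    warning("model ", model_id, ": R-hat >= 1.1 for a reported effect parameter")
  }
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, paste0("model", bundle$model_id, "_"))
  if (!is.null(bundle$contrasts)) {
    readr::write_csv(bundle$contrasts, paste0(pre, "contrasts.csv"))
  }
  if (!is.null(bundle$pairs)) {
    readr::write_csv(bundle$pairs, paste0(pre, "effect_pairs.csv"))
    readr::write_csv(rbind(bundle$slope, bundle$intercept),
                     paste0(pre, "slope.csv"))
  }
  readr::write_csv(bundle$rhat, paste0(pre, "rhat.csv"))
  if (length(bundle$drop_report) > 0) {
    readr::write_csv(tibble::tibble(reason = names(bundle$drop_report),
                                    n = unname(bundle$drop_report)),
                     paste0(pre, "drop_report.csv"))
  }
  cfg <- bundle$fit$config
  jsonlite::write_json(
    list(model_id = bundle$model_id, mcmc = unclass(cfg),
         prior = unclass(bundle$fit$prior), converged = bundle$converged),
    paste0(pre, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Parameter-recovery and calibration suite
#'
#' Generates replicate synthetic datasets, fits the requested models at
#' (typically reduced) MCMC settings, and scores the fits against the
#' generative ground truth: empirical 95%-HPDI coverage of the crop
#' contrasts and the consecutive-cotton slope, bias of the
#' consecutive-cotton slope, and the fraction of fits whose reported
#' effect parameters all have R-hat below 1.1.
#'
#' The Model-1 truth is estimand-aligned: under the generative model the
#' consecutive-cotton penalty acts on every record whose previous crop
#' was cotton, so the crop-vs-cotton estimand Model 1 identifies is
#' `crop_effect - consec_effect * mean(consecutive years among the kept
#' cotton-reference rows)`; the suite computes that implied truth from
#' each realized simulation.
#'
#' @param n_reps Number of replicate datasets.
#' @param sim Named list of [sim_config()] overrides applied to every
#'   replicate (the per-replicate `master_seed` is managed internally).
#' @param mcmc [mcmc_config()] used for every fit.
#' @param models Subset of `c(1, 4)` to fit and score.
#' @param seed Master seed for the whole suite.
#' @return List with `intervals` (one row per scored interval: `rep`,
#'   `model`, `label`, `true_value`, `post_mean`, `hpdi_low`,
#'   `hpdi_high`, `covered`), `coverage`, `consec_bias`,
#'   `consec_rel_bias`, `rhat_ok_frac`, `n_reps`.
#' @export
run_recovery <- function(n_reps = 50L, sim = list(),
                         mcmc = mcmc_config(n_chains = 3, n_iter = 2000,
                                            n_burn = 1000, seed = 1L),
                         models = c(1, 4), seed = 1L) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- list()
  rhat_ok <- logical(0)
  consec_err <- numeric(0)
  consec_truth <- NA_real_

  for (r in seq_len(n_reps)) {
    cfg <- do.call(sim_config, c(sim, list(master_seed = rep_seeds[r])))
    sim_out <- simulate_records(cfg)
    rec <- sim_out$records
    truth <- sim_out$truth
    mcmc_r <- mcmc
    mcmc_r$seed <- rep_seeds[r]

    if (1 %in% models) {
      b1 <- suppressWarnings(run_model(1, rec, mcmc = mcmc_r))
      rhat_ok <- c(rhat_ok, b1$converged)
      # implied estimand per realized replicate (see above)
      kept <- b1$design$rows
      tr <- truth$records
      key <- paste(tr$field_id, tr$year)
      kept_tr <- tr[match(paste(kept$field_id, kept$year), key), ]
      ref_consec <- mean(kept_tr$consec_cotton[kept_tr$prior_crop == "cotton"])
      ct <- b1$contrasts
      ct <- ct[ct$available & grepl(" vs cotton$", ct$label) &
                 ct$label != "cotton vs cotton", ]
      crop <- sub(" vs cotton$", "", ct$label)
      implied <- truth$crop_yield_effects[crop] -
        truth$consec_cotton_effect * ref_consec
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, model = 1L, label = ct$label,
        true_value = unname(implied), post_mean = ct$post_mean,
        hpdi_low = ct$hpdi_low, hpdi_high = ct$hpdi_high,
        covered = ct$hpdi_low <= implied & implied <= ct$hpdi_high)
    }
    if (4 %in% models) {
      b4 <- suppressWarnings(run_model(4, rec, mcmc = mcmc_r))
      rhat_ok <- c(rhat_ok, b4$converged)
      sl <- b4$contrasts[b4$contrasts$label == "per consecutive cotton year", ]
      consec_truth <- truth$consec_cotton_effect
      consec_err <- c(consec_err, sl$post_mean - consec_truth)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, model = 4L, label = sl$label,
        true_value = consec_truth, post_mean = sl$post_mean,
        hpdi_low = sl$hpdi_low, hpdi_high = sl$hpdi_high,
        covered = sl$hpdi_low <= consec_truth & consec_truth <= sl$hpdi_high)
    }
  }

  intervals <- do.call(rbind, rows)
  list(
    intervals = intervals,
    coverage = mean(intervals$covered),
    consec_bias = if (length(consec_err)) mean(consec_err) else NA_real_,
    consec_rel_bias = if (length(consec_err) && is.finite(consec_truth) &&
                          consec_truth != 0) {
      mean(consec_err) / abs(consec_truth)
    } else NA_real_,
    rhat_ok_frac = mean(rhat_ok),
    n_reps = n_reps
  )
}

#' Plot contrast summaries
#'
#' Point-and-interval plot of the crop contrasts against cotton (posterior
#' mean and 95% HPDI), with intervals excluding zero highlighted.
#'
#' @param contrasts A [crop_contrasts()] table.
#' @param xlab Axis label for the effect scale.
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts, xlab = "effect vs cotton") {
  dat <- contrasts[contrasts$available & contrasts$label != "cotton vs cotton", ]
  dat$label <- factor(dat$label, levels = dat$label[order(dat$post_mean)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$post_mean, y = .data$label,
                                    colour = .data$flagged)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpdi_low,
                                          xmax = .data$hpdi_high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"),
                                 guide = "none") +
    ggplot2::labs(x = xlab, y = NULL)
}

#' Plot the effect regression
#'
#' Scatter of the 14 crop effect pairs with the posterior-mean regression
#' line and a 95% HPDI band for the fitted line.
#'
#' @param reg A [fit_effect_regression()] result.
#' @return A ggplot object.
#' @export
plot_effect_regression <- function(reg) {
  pairs <- reg$pairs
  a <- pooled_draws(reg$fit, "(Intercept)")
  b <- pooled_draws(reg$fit, "slope")
  xg <- seq(min(pairs$lygus_effect), max(pairs$lygus_effect), length.out = 50)
  band <- t(vapply(xg, function(x0) {
    fx <- a + b * x0
    h <- hpdi(fx)
    c(mean(fx), h[["lower"]], h[["upper"]])
  }, numeric(3)))
  band_df <- tibble::tibble(x = xg, fit = band[, 1],
                            lo = band[, 2], hi = band[, 3])
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$lygus_effect,
                                      y = .data$yield_effect)) +
    ggplot2::geom_ribbon(data = band_df,
                         ggplot2::aes(x = .data$x, ymin = .data$lo,
                                      ymax = .data$hi),
                         inherit.aes = FALSE, alpha = 0.2, fill = "blue") +
    ggplot2::geom_line(data = band_df,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::labs(x = "effect on June Lygus (insects/sweep, vs cotton)",
                  y = "effect on yield (kg/ha, vs cotton)")
}
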