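#' The June averaging window
#'
#' Day-of-year window over which sweep-net samples are averaged to give the
#' "mean June Lygus density" response. Defaults to calendar June in a
#' non-leap year: days 152--181 inclusive.
#'
#' @param start_day,end_day Day-of-year bounds, inclusive; `start_day`
#'   must be strictly less than `end_day`.
#' @return An object of class `june_window`.
#' @export
june_window <- function(start_day = 152L, end_day = 181L) {
  stopifnot(start_day < end_day)
  structure(list(start_day = as.numeric(start_day),
                 end_day = as.numeric(end_day)),
            class = "june_window")
}

#' Time-averaged sweep density over a window
#'
#' Pest-control advisers sample on irregular dates, so successive sweep
#' counts are converted to a mean density by integrating the piecewise
#' linear interpolant of density versus time (trapezoid rule) and dividing
#' by the number of days covered. The integral is restricted to the
#' intersection of the sampled span `[first day, last day]` with the
#' window; samples outside the window contribute only through interpolated
#' values at the window boundary they straddle.
#'
#' @param day Numeric vector of sample days of year.
#' @param density Matching vector of densities (insects per sweep).
#' @param window A [june_window()].
#' @return Mean density over the covered part of the window (insects per
#'   sweep), or `NA_real_` when the samples do not cover any part of the
#'   window. A single in-window sample returns its own density.
#' @examples
#' mean_density(c(152, 162), c(0, 10))   # linear ramp: 5
#' @export
mean_density <- function(day, density, window = june_window()) {
  stopifnot(length(day) == length(density), length(day) >= 1)
  o <- order(day)
  day <- as.numeric(day[o])
  density <- as.numeric(density[o])
  lo <- max(min(day), window$start_day)
  hi <- min(max(day), window$end_day)
  if (lo > hi) return(NA_real_)
  if (length(day) == 1) return(density)
  if (lo == hi) {
    return(approx(day, density, xout = lo, ties = "ordered")$y)
  }
  knots <- sort(unique(c(lo, day[day > lo & day < hi], hi)))
  yk <- approx(day, density, xout = knots, ties = "ordered")$y
  area <- sum(diff(knots) * (head(yk, -1) + tail(yk, -1)) / 2)
  area / (hi - lo)
}

#' Consecutive prior cotton plantings
#'
#' Length of the unbroken run of cotton years immediately preceding the
#' focal season, capped at 4 (position 1 of the history is the year
#' before). A record is only eligible when its rotation record is complete
#' for the previous 4 years; otherwise `NA_integer_` is returned and the
#' record is excluded from the consecutive-cotton models.
#'
#' @param history Character vector of prior crops, position 1 = the year
#'   immediately before; entries are crop names or `NA`.
#' @return Integer in 0..4, or `NA_integer_` when fewer than 4 of the
#'   first 4 entries are known.
#' @examples
#' consecutive_cotton(c("cotton", "cotton", "wheat", "cotton"))  # 2
#' @export
consecutive_cotton <- function(history) {
  history <- as.character(history)
  if (length(history) < 4 || anyNA(history[1:4])) return(NA_integer_)
  run <- 0L
  for (k in 1:4) {
    if (identical(history[k], "cotton")) run <- run + 1L else break
  }
  run
}

#' Build a model-ready design from validated records
#'
#' Turns a record set into the response vector, fixed-effect matrix and
#' field/year grouping indices for one of the four mixed models:
#'
#' * Model 1 -- lint yield on prior-crop identity (cotton reference),
#'   species, and the 15 surrounding-crop counts;
#' * Model 2 -- mean June Lygus density on the same covariates;
#' * Model 4 -- lint yield on the number of consecutive prior cotton
#'   plantings (1--4), species, and the surrounding cotton count;
#' * Model 5 -- mean June Lygus density on the Model-4 covariates.
#'
#' Prior crop is coded with cotton as the reference category, so each crop
#' coefficient is directly the contrast against cotton. Rows are dropped
#' (complete-case) when the response is missing, the prior crop is unknown
#' (Models 1/2), the surrounding-crop data are missing, the 4-year
#' rotation record is incomplete (Models 4/5), or -- unless
#' `include_zero = TRUE` -- the previous crop was not cotton (Models 4/5,
#' matching the predictor's 1--4 range). The drop report accounts for
#' every input row exactly once.
#'
#' @param records An [fy_records] object.
#' @param model_id One of 1, 2, 4, 5.
#' @param window [june_window()] used for the Lygus response (Models 2/5).
#' @param include_zero Logical; admit records whose previous crop was not
#'   cotton (consecutive count 0) into Models 4/5. Default `FALSE`.
#' @return An object of class `model_design`: list with `response`,
#'   `X` (fixed-effect matrix with column names), `fixed_names`,
#'   `field_index`, `year_index`, `field_levels`, `year_levels`,
#'   `drop_report` (named integer vector), `dropped_columns` (prior-crop
#'   columns removed because no kept row had that crop), `rows` (the kept
#'   `field_id`/`year` keys, sorted), and `model_id`.
#' @export
build_design <- function(records, model_id, window = june_window(),
                         include_zero = FALSE) {
  stopifnot(inherits(records, "fy_records"), model_id %in% c(1, 2, 4, 5))
  f <- records$fields
  f <- f[order(f$field_id, f$year), ]
  n <- nrow(f)
  if (n == 0) stop("no records")

  if (model_id %in% c(1, 4)) {
    response <- f$yield_kg_ha
  } else {
    response <- vapply(seq_len(n), function(i) {
      s <- lygus_samples_for(records, f$field_id[i], f$year[i])
      if (nrow(s) == 0) return(NA_real_)
      mean_density(s$day_of_year, s$density_per_sweep, window)
    }, numeric(1))
  }

  prior_cols <- paste0("prior_crop_", 1:10)
  adj_cols <- paste0("adj_", crop_vocabulary())
  adj <- as.matrix(f[adj_cols])
  adj_missing <- apply(adj, 1, anyNA)
  consec <- vapply(seq_len(n), function(i) {
    consecutive_cotton(unlist(f[i, prior_cols], use.names = FALSE))
  }, integer(1))

  reason <- rep(NA_character_, n)
  reason[is.na(response)] <- "missing_response"
  if (model_id %in% c(1, 2)) {
    reason[is.na(reason) & is.na(f$prior_crop_1)] <- "missing_prior_crop"
  } else {
    reason[is.na(reason) & is.na(consec)] <- "incomplete_history"
    if (!include_zero) {
      reason[is.na(reason) & consec == 0L] <- "zero_consecutive_cotton"
    }
  }
  reason[is.na(reason) & adj_missing] <- "missing_adjacency"

  keep <- is.na(reason)
  reasons_order <- if (model_id %in% c(1, 2)) {
    c("missing_response", "missing_prior_crop", "missing_adjacency")
  } else {
    c("missing_response", "incomplete_history", "zero_consecutive_cotton",
      "missing_adjacency")
  }
  drop_report <- vapply(reasons_order, function(r) sum(reason == r, na.rm = TRUE),
                        integer(1))
  if (!any(keep)) {
    stop("no eligible rows for model ", model_id, " (dropped: ",
         paste(names(drop_report), drop_report, sep = "=", collapse = ", "), ")")
  }

  fk <- f[keep, ]
  yk <- response[keep]
  species_upland <- as.numeric(fk$species == "upland")
  dropped_columns <- character()

  if (model_id %in% c(1, 2)) {
    noncotton <- setdiff(crop_vocabulary(), "cotton")
    ind <- vapply(noncotton, function(cr) as.numeric(fk$prior_crop_1 == cr),
                  numeric(nrow(fk)))
    if (nrow(fk) == 1) ind <- matrix(ind, nrow = 1, dimnames = list(NULL, noncotton))
    colnames(ind) <- paste0("prior_", noncotton)
    present <- colSums(ind) > 0
    dropped_columns <- colnames(ind)[!present]
    ind <- ind[, present, drop = FALSE]
    adj_k <- as.matrix(fk[adj_cols])
    X <- cbind("(Intercept)" = 1, ind, species_upland = species_upland, adj_k)
  } else {
    consec_k <- as.numeric(consec[keep])
    X <- cbind("(Intercept)" = 1, consec_cotton = consec_k,
               species_upland = species_upland,
               adj_cotton = as.numeric(fk$adj_cotton))
  }
  storage.mode(X) <- "double"

  field_levels <- sort(unique(fk$field_id))
  year_levels <- sort(unique(fk$year))
  structure(list(
    response = as.numeric(yk),
    X = X,
    fixed_names = colnames(X),
    field_index = match(fk$field_id, field_levels),
    year_index = match(fk$year, year_levels),
    field_levels = field_levels,
    year_levels = year_levels,
    drop_report = drop_report,
    dropped_columns = dropped_columns,
    rows = tibble::tibble(field_id = fk$field_id, year = fk$year),
    model_id = model_id
  ), class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat("<model_design> model ", x$model_id, ": ", length(x$response),
      " rows, ", ncol(x$X), " fixed effects, ", length(x$field_levels),
      " fields, ", length(x$year_levels), " years\n", sep = "")
  dr <- x$drop_report
  cat("dropped:", paste(names(dr), dr, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
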