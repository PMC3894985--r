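#' Prior specification for the mixed model
#'
#' Noninformative priors: each fixed effect is Normal(0, `beta_sd`^2) and
#' all three variance parameters (residual, field, year) get an
#' inverse-gamma prior with the given shape and scale.
#'
#' @param beta_sd Prior standard deviation of each fixed effect.
#' @param ig_shape,ig_scale Inverse-gamma hyperparameters shared by the
#'   residual and random-effect variances.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(beta_sd = 100, ig_shape = 0.001, ig_scale = 0.001) {
  stopifnot(beta_sd > 0, ig_shape > 0, ig_scale > 0)
  structure(list(beta_sd = beta_sd, ig_shape = ig_shape, ig_scale = ig_scale),
            class = "prior_spec")
}

#' MCMC protocol configuration
#'
#' Defaults follow the standard protocol for these models: three chains of
#' 10,000 iterations each, with the first 5,000 discarded as burn-in and
#' no thinning; inference pools the remaining 15,000 draws.
#'
#' @param n_chains Number of chains (at least 2 for convergence
#'   diagnostics).
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded from each chain.
#' @param seed Master seed; chain k draws its own substream seed from it,
#'   so a fit is bit-reproducible given `(design, prior, config)`.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 10000L, n_burn = 5000L,
                        seed = 1L) {
  stopifnot(n_chains >= 1, n_burn >= 0, n_burn < n_iter)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Gaussian full conditional of the fixed effects
#'
#' Closed-form conditional posterior of beta given the random effects and
#' the residual variance: covariance `(X'X/sigma2 + I/beta_sd^2)^-1`, mean
#' `cov %*% X'(y - u - v)/sigma2`. This is the analytic building block the
#' Gibbs sampler cycles through; it is exported so the sampler can be
#' checked against it directly.
#'
#' @param design A [build_design()] object (or any list with `response`,
#'   `X`, `field_index`, `year_index`).
#' @param u Field effects, one per field level (recycled to rows via
#'   `field_index`); `NULL` for none.
#' @param v Year effects, one per year level; `NULL` for none.
#' @param sigma2 Residual variance (> 0).
#' @param prior A [prior_spec()].
#' @return List with `mean` (length-p vector) and `cov` (p x p matrix).
#' @export
beta_full_conditional <- function(design, u = NULL, v = NULL, sigma2,
                                  prior = prior_spec()) {
  stopifnot(sigma2 > 0)
  X <- design$X
  y <- design$response
  ue <- if (is.null(u)) 0 else u[design$field_index]
  ve <- if (is.null(v)) 0 else v[design$year_index]
  p <- ncol(X)
  A <- crossprod(X) / sigma2 + diag(p) / prior$beta_sd^2
  qrA <- qr(A)
  if (qrA$rank < p) {
    bad <- colnames(X)[qrA$pivot[(qrA$rank + 1):p]]
    stop("singular fixed-effect system; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  cov <- solve(A)
  m <- drop(cov %*% crossprod(X, y - ue - ve) / sigma2)
  list(mean = setNames(m, colnames(X)), cov = cov)
}

#' Inverse-gamma full conditional of a variance parameter
#'
#' Conjugate update used for the residual variance (on the residual
#' vector), the field-effect variance (on the field effects) and the
#' year-effect variance (on the year effects): posterior shape is
#' `ig_shape + n/2`, posterior scale is `ig_scale + sum(x^2)/2`.
#'
#' @param x Numeric vector (residuals or effects), non-empty.
#' @param prior A [prior_spec()].
#' @return Named numeric vector `c(shape, scale)`.
#' @export
variance_full_conditional <- function(x, prior = prior_spec()) {
  stopifnot(length(x) >= 1)
  c(shape = prior$ig_shape + length(x) / 2,
    scale = prior$ig_scale + sum(x^2) / 2)
}

#' Fit the hierarchical Bayesian linear mixed model by Gibbs sampling
#'
#' Samples the posterior of `y = X beta + u[field] + v[year] + eps` under
#' the [prior_spec()] priors by cycling through the exact conjugate full
#' conditionals: beta jointly Gaussian, each field and year effect
#' Gaussian, and the three variances inverse-gamma. The model is fully
#' conjugate, so the Gibbs sampler targets the identical posterior a
#' Hamiltonian sampler would, with no tuning.
#'
#' Chains start from beta = 0 and zero random effects, with variances
#' initialised near the response variance and per-chain jitter drawn from
#' the master seed (chain k uses substream seed k), giving reproducibly
#' "random" initialisations. Variance draws are floored at 1e-12; the
#' number of floor hits is reported per chain.
#'
#' @param design A [build_design()] object, or a compatible list with
#'   `response`, `X`, `field_index`, `year_index` (indices may be `NULL`
#'   or empty to disable a random effect, as in the effect
#'   meta-regression).
#' @param prior A [prior_spec()].
#' @param config An [mcmc_config()].
#' @param fixed_sigma2 Optionally pin the residual variance at a known
#'   value instead of sampling it (used for analytic checks).
#' @param recenter Logical; sweep the random-effect means into the
#'   intercept after each update. Off by default: the zero-mean priors
#'   identify the model and the conditionals mix acceptably at the
#'   problem sizes this package targets.
#' @return Object of class `posterior_samples`: per-chain post-burn-in
#'   draw matrices for `beta` (columns labelled by `fixed_names`), `u`,
#'   `v`, and vectors for `sigma2`, `sigma2_field`, `sigma2_year`, plus
#'   the design labels, prior and config.
#' @export
gibbs_fit <- function(design, prior = prior_spec(), config = mcmc_config(),
                      fixed_sigma2 = NULL, recenter = FALSE) {
  y <- as.numeric(design$response)
  X <- design$X
  stopifnot(is.matrix(X), nrow(X) == length(y))
  fi <- design$field_index
  yi <- design$year_index
  if (is.null(fi)) fi <- integer(0)
  if (is.null(yi)) yi <- integer(0)
  n_field <- if (length(fi)) max(fi) else 0L
  n_year <- if (length(yi)) max(yi) else 0L
  p <- ncol(X)
  intercept_col <- match("(Intercept)", colnames(X), nomatch = 0L)

  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, config$n_chains)

  vy <- var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed(chain_seeds[k])
    beta0 <- rnorm(p, 0, 0.01 * sqrt(vy))
    s2_0 <- vy * exp(runif(1, -0.5, 0.5))
    s2f_0 <- vy / 4 * exp(runif(1, -0.5, 0.5))
    s2y_0 <- vy / 4 * exp(runif(1, -0.5, 0.5))
    res <- .gibbs_chain(
      y, X, as.integer(fi), as.integer(yi), as.integer(n_field),
      as.integer(n_year), prior$beta_sd, prior$ig_shape, prior$ig_scale,
      config$n_iter, config$n_burn,
      beta0, rep(0, n_field), rep(0, n_year),
      s2_0, s2f_0, s2y_0,
      !is.null(fixed_sigma2), if (is.null(fixed_sigma2)) 0 else fixed_sigma2,
      recenter, intercept_col)
    colnames(res$beta) <- colnames(X)
    if (n_field > 0) colnames(res$u) <- design$field_levels
    if (n_year > 0) colnames(res$v) <- as.character(design$year_levels)
    res$sigma2 <- as.vector(res$sigma2)
    res$sigma2_field <- as.vector(res$sigma2_field)
    res$sigma2_year <- as.vector(res$sigma2_year)
    chains[[k]] <- res
  }

  structure(list(
    chains = chains,
    fixed_names = colnames(X),
    field_levels = if (n_field > 0) design$field_levels else character(),
    year_levels = if (n_year > 0) design$year_levels else character(),
    dropped_columns = design$dropped_columns,
    model_id = design$model_id,
    prior = prior,
    config = config,
    fixed_sigma2 = fixed_sigma2
  ), class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  nk <- nrow(x$chains[[1]]$beta)
  cat("<posterior_samples> ", length(x$chains), " chains x ", nk,
      " post-burn-in draws; ", length(x$fixed_names), " fixed effects, ",
      length(x$field_levels), " fields, ", length(x$year_levels),
      " years\n", sep = "")
  invisible(x)
}

#' Extract draws from a fit
#'
#' `chain_draws()` returns one matrix (draws x chains) for a single named
#' parameter; `pooled_draws()` concatenates the chains into one vector,
#' the form all posterior summaries are computed from.
#'
#' @param fit A [gibbs_fit()] result.
#' @param parameter Name of a fixed effect (as in `fit$fixed_names`), or
#'   `"sigma2"`, `"sigma2_field"`, `"sigma2_year"`, or `"u:<field>"` /
#'   `"v:<year>"` for individual random effects.
#' @return A matrix (`chain_draws`) or numeric vector (`pooled_draws`).
#' @export
chain_draws <- function(fit, parameter) {
  stopifnot(inherits(fit, "posterior_samples"))
  get1 <- function(ch) {
    if (parameter %in% colnames(ch$beta)) return(ch$beta[, parameter])
    if (parameter %in% c("sigma2", "sigma2_field", "sigma2_year")) {
      d <- ch[[parameter]]
      if (length(d) == 0) stop("no draws for ", parameter,
                               " (random effect not in model)")
      return(d)
    }
    if (startsWith(parameter, "u:")) return(ch$u[, sub("^u:", "", parameter)])
    if (startsWith(parameter, "v:")) return(ch$v[, sub("^v:", "", parameter)])
    stop("unknown parameter: ", parameter)
  }
  vapply(fit$chains, get1, numeric(nrow(fit$chains[[1]]$beta)))
}

#' @rdname chain_draws
#' @export
pooled_draws <- function(fit, parameter) {
  as.vector(chain_draws(fit, parameter))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) diagnostic: with m chains of n draws, W the mean
#' within-chain variance and B = n * variance of the chain means, returns
#' `sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate the chains have
#' mixed; this package warns at 1.1. When the within-chain variance is
#' zero the diagnostic is undefined and `NA_real_` is returned (never a
#' silent 1).
#'
#' @param draws Matrix with one column per chain, or a list of equal
#'   length numeric vectors.
#' @return The potential scale reduction factor, or `NA_real_` when
#'   undefined.
#' @export
rhat <- function(draws) {
  if (is.list(draws)) {
    n <- unique(lengths(draws))
    stopifnot(length(n) == 1)
    draws <- matrix(unlist(draws), ncol = length(draws))
  }
  stopifnot(is.matrix(draws), ncol(draws) >= 2, nrow(draws) >= 2)
  n <- nrow(draws)
  W <- mean(apply(draws, 2, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * var(colMeans(draws))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for every monitored parameter
#'
#' @param fit A [gibbs_fit()] result.
#' @param parameters Parameters to monitor; defaults to all fixed effects
#'   plus the variance parameters present in the model.
#' @return Tibble with columns `parameter` and `rhat`.
#' @export
rhat_table <- function(fit, parameters = NULL) {
  if (is.null(parameters)) {
    parameters <- fit$fixed_names
    if (length(fit$chains[[1]]$sigma2) > 0) parameters <- c(parameters, "sigma2")
    if (length(fit$chains[[1]]$sigma2_field) > 0) parameters <- c(parameters, "sigma2_field")
    if (length(fit$chains[[1]]$sigma2_year) > 0) parameters <- c(parameters, "sigma2_year")
  }
  tibble::tibble(
    parameter = parameters,
    rhat = vapply(parameters, function(pp) rhat(chain_draws(fit, pp)), numeric(1))
  )
}

#' Serialize posterior draws
#'
#' Writes one row per retained draw (chain, iteration, then one column per
#' fixed effect and variance parameter) plus a JSON sidecar with the
#' prior, MCMC config, convergence table and variance floor-hit counts.
#'
#' @param fit A [gibbs_fit()] result.
#' @param path CSV destination.
#' @param json_path Optional sidecar destination.
#' @return `invisible(NULL)`.
#' @export
write_posterior <- function(fit, path, json_path = NULL) {
  tabs <- lapply(seq_along(fit$chains), function(k) {
    ch <- fit$chains[[k]]
    out <- data.frame(chain = k, iteration = seq_len(nrow(ch$beta)),
                      ch$beta, check.names = FALSE)
    out$sigma2 <- ch$sigma2
    if (length(ch$sigma2_field) > 0) out$sigma2_field <- ch$sigma2_field
    if (length(ch$sigma2_year) > 0) out$sigma2_year <- ch$sigma2_year
    out
  })
  readr::write_csv(do.call(rbind, tabs), path)
  if (!is.null(json_path)) {
    side <- list(
      prior = unclass(fit$prior),
      config = unclass(fit$config),
      rhat = rhat_table(fit),
      floor_hits = vapply(fit$chains, function(ch) ch$floor_hits, integer(1))
    )
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(NULL)
}
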