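# Bayesian constraint of the linear CUE temperature response
#   CUE = CUE0 + m (T - T0),    T0 = 20 degC by convention,
# by random-walk Metropolis-Hastings over (CUE0, m, sigma) under box-uniform
# priors, with multi-chain Gelman-Rubin diagnostics and histogram-mode point
# estimates pooled across chains.

#' Linear temperature-response parameters
#'
#' @param cue0 CUE at the reference temperature, in (0, 1).
#' @param m Temperature response coefficient (change in CUE per degC), in
#'   (-0.1, 0\].
#' @param t0 Reference temperature in degC; 20 by convention.
#' @param sigma Observation-noise SD in CUE units, > 0 (optional, `NA` if the
#'   parameters are used only for prediction).
#' @return List of class `cue_temp_params`.
#' @export
temperature_response_params <- function(cue0, m, t0 = 20, sigma = NA_real_) {
  stopifnot(is.numeric(cue0), cue0 > 0, cue0 < 1,
            is.numeric(m), m > -0.1, m <= 0,
            is.numeric(t0))
  if (!is.na(sigma)) stopifnot(sigma > 0)
  structure(list(cue0 = cue0, m = m, t0 = t0, sigma = sigma),
            class = "cue_temp_params")
}

#' Predict CUE from the linear temperature response
#'
#' `CUE = cue0 + m (temp - t0)`. No clipping: for temperatures far from the
#' reference the line can leave (0, 1), which is the caller's concern.
#'
#' @param params List with elements `cue0`, `m` and optionally `t0`
#'   (default 20), e.g. from [temperature_response_params()].
#' @param temp Temperature(s) in degC.
#' @return Predicted CUE, same length as `temp`.
#' @export
#' @examples
#' predict_cue(list(cue0 = 0.475, m = -0.016), temp = 20)
predict_cue <- function(params, temp) {
  t0 <- if (is.null(params$t0)) 20 else params$t0
  params$cue0 + params$m * (temp - t0)
}

#' Box-uniform prior specification
#'
#' Independent uniform priors over intervals for the intercept `cue0`, slope
#' `m`, and noise SD `sigma`.
#'
#' @param cue0 Interval (low, high) for `cue0`; default (0, 1).
#' @param m Interval for `m`; default (-0.1, 0).
#' @param sigma Interval for `sigma`; default (0.001, 1).
#' @return List of class `cue_prior_box`.
#' @export
prior_box <- function(cue0 = c(0, 1), m = c(-0.1, 0), sigma = c(0.001, 1)) {
  for (iv in list(cue0, m, sigma))
    if (length(iv) != 2 || iv[1] >= iv[2])
      stop("each prior interval must be (low, high) with low < high")
  structure(list(cue0 = cue0, m = m, sigma = sigma), class = "cue_prior_box")
}

#' Sampler configuration
#'
#' @param n_chains Number of independent chains (>= 2 for diagnostics);
#'   default 5.
#' @param n_iterations Iterations per chain; default 100000.
#' @param burn_in Iterations discarded from the start of each chain; default
#'   1000 (must be < `n_iterations`).
#' @param proposal_scales Per-parameter Gaussian random-walk step SDs, in the
#'   order (cue0, m, sigma); defaults are ~2% of each prior range.
#' @param adapt_during_burn_in If `TRUE` (default) step scales are tuned
#'   toward ~25% acceptance during burn-in only, then frozen, so the retained
#'   chain is exact Metropolis-Hastings.
#' @param thin Keep every `thin`-th post-burn-in sample when pooling;
#'   default 1 (no thinning).
#' @param seed Master RNG seed; per-chain sub-seeds are derived from it
#'   deterministically. `NULL` uses the current RNG state.
#' @return List of class `cue_chain_config`.
#' @export
chain_config <- function(n_chains = 5, n_iterations = 100000, burn_in = 1000,
                         proposal_scales = c(cue0 = 0.02, m = 0.002, sigma = 0.02),
                         adapt_during_burn_in = TRUE, thin = 1, seed = NULL) {
  stopifnot(n_chains >= 1, n_iterations >= 1, burn_in >= 0,
            burn_in < n_iterations, thin >= 1)
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 burn_in = burn_in, proposal_scales = proposal_scales,
                 adapt_during_burn_in = isTRUE(adapt_during_burn_in),
                 thin = as.integer(thin), seed = seed),
            class = "cue_chain_config")
}

.in_box <- function(theta, priors, sigma_fixed = NULL) {
  ok <- theta[1] > priors$cue0[1] && theta[1] < priors$cue0[2] &&
    theta[2] > priors$m[1] && theta[2] < priors$m[2]
  if (is.null(sigma_fixed))
    ok <- ok && theta[3] > priors$sigma[1] && theta[3] < priors$sigma[2]
  ok
}

#' Unnormalized log-posterior of the temperature-response model
#'
#' Independent Gaussian observation errors: each CUE value is modelled as
#' Normal with mean `cue0 + m (temp - t0)` and SD `sigma`. Outside the prior
#' box the log-posterior is `-Inf`; inside, the flat priors contribute only a
#' constant, so the value equals the Gaussian log-likelihood.
#'
#' @param theta Parameter vector `(cue0, m, sigma)` — or `(cue0, m)` when
#'   `sigma_fixed` is given.
#' @param temp,cue Paired observation vectors (equal length, finite,
#'   non-empty).
#' @param priors A [prior_box()].
#' @param t0 Reference temperature, default 20 degC.
#' @param sigma_fixed Optional known noise SD; when supplied, `theta` has two
#'   elements and sigma is not a parameter.
#' @return Scalar unnormalized log-density.
#' @export
log_posterior <- function(theta, temp, cue, priors = prior_box(), t0 = 20,
                          sigma_fixed = NULL) {
  if (length(temp) == 0 || length(cue) == 0) stop("data must be non-empty")
  if (length(temp) != length(cue)) stop("temp and cue lengths differ")
  if (any(!is.finite(temp)) || any(!is.finite(cue)))
    stop("temp and cue must be finite")
  if (!.in_box(theta, priors, sigma_fixed)) return(-Inf)
  sigma <- if (is.null(sigma_fixed)) theta[3] else sigma_fixed
  resid <- cue - theta[1] - theta[2] * (temp - t0)
  n <- length(cue)
  # closed form of sum(dnorm(..., log = TRUE)); cheaper in the sampler loop
  -n * log(sigma) - n * log(2 * pi) / 2 - sum(resid * resid) / (2 * sigma^2)
}

#' Random-walk Metropolis-Hastings sampler
#'
#' Symmetric per-parameter Gaussian proposals; a proposal is accepted with
#' probability `min(1, exp(delta log-posterior))`, and proposals outside the
#' prior support (log-posterior `-Inf`) are always rejected. With
#' `adapt_during_burn_in`, step scales are multiplied by
#' `exp(rate - 0.25)` every 100 iterations during burn-in and frozen
#' afterwards; the post-burn-in chain is therefore exact M-H. The same seed
#' always reproduces the identical chain.
#'
#' @param log_post Function mapping a parameter vector to an unnormalized
#'   log-density (`-Inf` outside the support).
#' @param init Numeric start vector; must have finite `log_post(init)`.
#' @param config A [chain_config()]; `n_chains` is ignored here (one chain).
#' @param seed Integer seed for this chain; `NULL` uses the current RNG
#'   state.
#' @return List of class `cue_mcmc_chain`: `samples` (iterations x
#'   parameters matrix, burn-in included), `log_post` values, overall
#'   `acceptance_rate`, post-burn-in `acceptance_rate_post`, `burn_in`,
#'   `scales_final`, `seed_used`.
#' @export
metropolis_hastings <- function(log_post, init, config = chain_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  scales <- rep_len(as.numeric(config$proposal_scales), d)
  lp <- log_post(init)
  if (!is.finite(lp)) stop("init has non-finite log-posterior (outside support?)")
  n <- config$n_iterations
  burn <- config$burn_in
  samples <- matrix(NA_real_, nrow = n, ncol = d)
  lps <- numeric(n)
  theta <- as.numeric(init)
  n_acc <- 0L
  n_acc_post <- 0L
  window_acc <- 0L
  for (i in seq_len(n)) {
    prop <- theta + stats::rnorm(d) * scales
    lp_prop <- log_post(prop)
    accept <- is.finite(lp_prop) &&
      (lp_prop >= lp || log(stats::runif(1)) < lp_prop - lp)
    if (accept) {
      theta <- prop
      lp <- lp_prop
      n_acc <- n_acc + 1L
      window_acc <- window_acc + 1L
      if (i > burn) n_acc_post <- n_acc_post + 1L
    }
    samples[i, ] <- theta
    lps[i] <- lp
    if (config$adapt_during_burn_in && i <= burn && i %% 100L == 0L) {
      rate <- window_acc / 100
      scales <- scales * exp(rate - 0.25)
      window_acc <- 0L
    }
  }
  colnames(samples) <- if (d == 3) c("cue0", "m", "sigma")
  else if (d == 2) c("cue0", "m") else paste0("par", seq_len(d))
  structure(list(samples = samples, log_post = lps,
                 acceptance_rate = n_acc / n,
                 acceptance_rate_post = if (n > burn) n_acc_post / (n - burn) else NA_real_,
                 burn_in = burn, scales_final = scales,
                 seed_used = if (is.null(seed)) NA_integer_ else seed),
            class = "cue_mcmc_chain")
}

.chain_matrix <- function(chains, parameter, discard_burn_in) {
  cols <- lapply(chains, function(ch) {
    if (inherits(ch, "cue_mcmc_chain")) {
      s <- ch$samples
      if (discard_burn_in && ch$burn_in > 0) s <- s[-seq_len(ch$burn_in), , drop = FALSE]
      if (is.null(parameter)) s[, 1] else s[, parameter]
    } else as.numeric(ch)
  })
  len <- unique(vapply(cols, length, integer(1)))
  if (length(len) != 1) stop("chains must have equal length after burn-in removal")
  if (len < 10) stop("chains too short for a diagnostic (need >= 10 samples)")
  do.call(cbind, cols)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between-/within-chain variance diagnostic: with `W` the mean within-chain
#' variance, `B/n` the variance of the chain means, and
#' `var+ = (n-1)/n W + B/n`, the statistic is `sqrt(var+/W)`. The
#' finite-sample deflation of `var+` can push the ratio marginally below 1
#' when the chains agree; since values below 1 carry no diagnostic meaning
#' the result is floored at 1, so identical chains give exactly 1. Chains
#' that are each constant but differ from one another (`W = 0`, `B > 0`)
#' give `Inf`.
#'
#' @param chains List (length >= 2) of `cue_mcmc_chain` objects or plain
#'   numeric vectors of equal length (>= 10 after burn-in removal).
#' @param parameter Column name to extract when `chains` are
#'   `cue_mcmc_chain` objects (e.g. `"cue0"`).
#' @param discard_burn_in Drop each chain's burn-in before computing
#'   (default `TRUE`; only applies to `cue_mcmc_chain` inputs).
#' @return Scalar R-hat, >= 1; values below ~1.1 indicate convergence.
#' @export
gelman_rubin <- function(chains, parameter = NULL, discard_burn_in = TRUE) {
  if (length(chains) < 2) stop("at least 2 chains are required")
  x <- .chain_matrix(chains, parameter, discard_burn_in)
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B_over_n <- stats::var(colMeans(x))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B_over_n
  max(1, sqrt(var_plus / W))
}

#' Histogram-mode point estimate of a marginal posterior
#'
#' Center of the highest-count histogram bin over the supplied interval.
#' Ties are broken toward the bin whose center is nearer the sample mean.
#'
#' @param samples Numeric vector (>= 100 values).
#' @param bin_width Histogram bin width (> 0).
#' @param interval Interval (low, high) to tile with bins; defaults to the
#'   sample range. Pass the prior interval to bound the estimate by the
#'   prior support.
#' @return Scalar mode estimate (a bin center).
#' @export
posterior_mode <- function(samples, bin_width, interval = range(samples)) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("need at least 100 samples for a mode estimate")
  if (bin_width <= 0) stop("bin_width must be positive")
  lo <- interval[1]
  n_bins <- max(1L, ceiling((interval[2] - lo) / bin_width - 1e-9))
  idx <- pmin(pmax(floor((samples - lo) / bin_width) + 1L, 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  best <- which(counts == max(counts))
  centers <- lo + (best - 0.5) * bin_width
  centers[which.min(abs(centers - mean(samples)))]
}

#' Constrain the CUE temperature response by multi-chain M-H sampling
#'
#' Runs `config$n_chains` independent Metropolis-Hastings chains on the
#' Gaussian-error linear model `cue ~ Normal(cue0 + m (temp - t0), sigma)`
#' under the box-uniform priors, each chain starting from an independent
#' uniform draw inside the box with a sub-seed derived from the master seed.
#' Burn-in is discarded, post-burn-in samples are pooled (optionally
#' thinned), and the summary reports histogram-mode point estimates,
#' posterior means, central 95% credible intervals, per-parameter
#' Gelman-Rubin R-hat, and per-chain acceptance rates. An R-hat above 1.1
#' raises a warning, not an error.
#'
#' @param ds Observation data.frame; rows with both `cue` in (0, 1) and a
#'   finite `incubation_temp` are used (>= 10 required). Records flagged by
#'   [derive_cue()] with CUE outside (0, 1) are thereby excluded.
#' @param priors A [prior_box()].
#' @param config A [chain_config()].
#' @param sigma_fixed Optional known noise SD; if supplied only (cue0, m)
#'   are sampled.
#' @param t0 Reference temperature, default 20 degC.
#' @param mode_bin_widths Histogram bin widths for the point estimates,
#'   named; defaults 0.005 (cue0), 0.0005 (m) — about 1/200 of each default
#'   prior range — and 1/200 of the sigma prior range.
#' @return Object of class `cue_posterior`: list with `point_estimates`,
#'   `posterior_means`, `credible_intervals` (2 x p), `gelman_rubin`,
#'   `per_chain_acceptance`, `pooled_sample_count`, `n_obs`, `chains`
#'   (list of `cue_mcmc_chain`), `priors`, `config`, `t0`, `sigma_fixed`.
#' @export
#' @examples
#' ds <- generate_cue_dataset(generator_config(n = 120, seed = 1))
#' fit <- run_inversion(ds, config = chain_config(n_chains = 2,
#'   n_iterations = 2000, burn_in = 500, seed = 1))
#' fit$point_estimates
run_inversion <- function(ds, priors = prior_box(), config = chain_config(),
                          sigma_fixed = NULL, t0 = 20,
                          mode_bin_widths = NULL) {
  keep <- !is.na(ds$cue) & ds$cue > 0 & ds$cue < 1 &
    !is.na(ds$incubation_temp) & is.finite(ds$incubation_temp)
  n_dropped <- sum(!is.na(ds$cue) & !is.na(ds$incubation_temp)) - sum(keep)
  if (n_dropped > 0)
    message(n_dropped, " record(s) with CUE outside (0,1) excluded from the inversion")
  temp <- ds$incubation_temp[keep]
  cue <- ds$cue[keep]
  n_obs <- length(cue)
  if (n_obs < 10)
    stop("need >= 10 records with both cue and incubation_temp; found ", n_obs)
  if (config$n_chains < 2)
    stop("n_chains must be >= 2 for convergence diagnostics")

  d <- if (is.null(sigma_fixed)) 3L else 2L
  par_names <- if (d == 3) c("cue0", "m", "sigma") else c("cue0", "m")
  log_post <- function(theta) log_posterior(theta, temp, cue, priors, t0,
                                            sigma_fixed)
  if (!is.null(config$seed)) set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)
  chains <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    set.seed(sub_seeds[k])
    init <- c(stats::runif(1, priors$cue0[1], priors$cue0[2]),
              stats::runif(1, priors$m[1], priors$m[2]),
              if (d == 3) stats::runif(1, priors$sigma[1], priors$sigma[2]))
    chains[[k]] <- metropolis_hastings(log_post, init, config, seed = sub_seeds[k])
  }

  post <- lapply(chains, function(ch)
    ch$samples[-seq_len(ch$burn_in), , drop = FALSE])
  if (config$thin > 1)
    post <- lapply(post, function(s)
      s[seq(1, nrow(s), by = config$thin), , drop = FALSE])
  pooled <- do.call(rbind, post)

  ranges <- list(cue0 = priors$cue0, m = priors$m, sigma = priors$sigma)
  widths <- c(cue0 = 0.005, m = 0.0005,
              sigma = diff(priors$sigma) / 200)
  if (!is.null(mode_bin_widths)) widths[names(mode_bin_widths)] <- mode_bin_widths
  point <- vapply(par_names, function(p)
    posterior_mode(pooled[, p], widths[[p]], interval = ranges[[p]]),
    numeric(1))
  means <- colMeans(pooled)
  ci <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975))
  rhat <- vapply(par_names, function(p) gelman_rubin(chains, p), numeric(1))
  if (any(rhat > 1.1))
    warning("Gelman-Rubin R-hat above 1.1 for: ",
            paste(par_names[rhat > 1.1], collapse = ", "),
            " -- chains may not have converged")

  structure(list(point_estimates = point, posterior_means = means,
                 credible_intervals = ci, gelman_rubin = rhat,
                 per_chain_acceptance = vapply(chains, `[[`, numeric(1),
                                               "acceptance_rate_post"),
                 pooled_sample_count = nrow(pooled), n_obs = n_obs,
                 chains = chains, priors = priors, config = config,
                 t0 = t0, sigma_fixed = sigma_fixed),
            class = "cue_posterior")
}

#' @export
print.cue_posterior <- function(x, ...) {
  cat("CUE temperature-response inversion (", length(x$chains), " chains, ",
      x$n_obs, " observations)\n", sep = "")
  cat("  CUE = cue0 + m (T - ", x$t0, ")\n", sep = "")
  tab <- data.frame(mode = x$point_estimates,
                    mean = x$posterior_means[names(x$point_estimates)],
                    ci_lower = x$credible_intervals[1, names(x$point_estimates)],
                    ci_upper = x$credible_intervals[2, names(x$point_estimates)],
                    r_hat = x$gelman_rubin)
  print(round(tab, 4))
  cat("  pooled samples:", x$pooled_sample_count,
      "| acceptance:", paste(sprintf("%.2f", x$per_chain_acceptance),
                             collapse = " "), "\n")
  invisible(x)
}
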