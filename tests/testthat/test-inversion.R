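test_that("the linear response predicts the reference value and off-reference points", {
  eq2 <- list(cue0 = 0.475, m = -0.016)
  expect_equal(predict_cue(eq2, 20), 0.475)
  expect_equal(predict_cue(eq2, 28), 0.347)
  expect_equal(predict_cue(list(cue0 = 0.3, m = -0.05, t0 = 10), 10), 0.3)
  expect_equal(predict_cue(eq2, c(20, 28)), c(0.475, 0.347))
})

test_that("log_posterior matches an independently coded Gaussian sum", {
  set.seed(2)
  temp <- runif(20, 2, 28)
  cue <- 0.5 - 0.01 * (temp - 20) + rnorm(20, 0, 0.1)
  theta <- c(0.48, -0.012, 0.15)
  oracle <- sum(log(1 / (0.15 * sqrt(2 * pi)) *
                      exp(-(cue - 0.48 + 0.012 * (temp - 20))^2 / (2 * 0.15^2))))
  expect_equal(log_posterior(theta, temp, cue), oracle)
  # single datum exactly on the line: the Gaussian peak density
  expect_equal(log_posterior(c(0.5, -0.01, 0.2), 20, 0.5),
               log(1 / (0.2 * sqrt(2 * pi))))
  # outside any prior face -> -Inf
  expect_identical(log_posterior(c(1.5, -0.01, 0.2), temp, cue), -Inf)
  expect_identical(log_posterior(c(0.5, 0.01, 0.2), temp, cue), -Inf)
  expect_identical(log_posterior(c(0.5, -0.01, 2), temp, cue), -Inf)
  expect_error(log_posterior(theta, numeric(0), numeric(0)), "non-empty")
})

test_that("the sampler is deterministic under a fixed seed", {
  lp <- function(th) log_posterior(th, c(10, 20, 25), c(0.6, 0.5, 0.4))
  cfg <- chain_config(n_iterations = 500, burn_in = 100)
  ch1 <- metropolis_hastings(lp, c(0.5, -0.01, 0.2), cfg, seed = 99)
  ch2 <- metropolis_hastings(lp, c(0.5, -0.01, 0.2), cfg, seed = 99)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$acceptance_rate, ch2$acceptance_rate)
  expect_error(metropolis_hastings(lp, c(2, 0, 0.2), cfg, seed = 1), "support")
})

test_that("acceptance behaves as the proposal geometry dictates", {
  # flat posterior over the unit box: every in-box proposal is accepted, so
  # the acceptance rate equals the chance a Gaussian step stays inside --
  # computable in closed form from the visited states
  flat <- function(th) if (all(th > 0 & th < 1)) 0 else -Inf
  s <- 0.05
  cfg <- chain_config(n_iterations = 10000, burn_in = 0,
                      proposal_scales = s, adapt_during_burn_in = FALSE)
  ch <- metropolis_hastings(flat, c(0.5, 0.5, 0.5), cfg, seed = 4)
  p_in <- mean(apply(ch$samples, 1, function(x)
    prod(pnorm((1 - x) / s) - pnorm(-x / s))))
  expect_equal(ch$acceptance_rate, p_in, tolerance = 0.02)
  expect_true(all(ch$samples > 0 & ch$samples < 1))
  # sharply peaked target with tiny steps: acceptance near 1
  peaked <- function(th) -sum((th - 0.5)^2) * 1e4
  cfg2 <- chain_config(n_iterations = 2000, burn_in = 0,
                       proposal_scales = 1e-4, adapt_during_burn_in = FALSE)
  ch2 <- metropolis_hastings(peaked, c(0.5, 0.5, 0.5), cfg2, seed = 4)
  expect_gt(ch2$acceptance_rate, 0.97)
})

test_that("Gelman-Rubin separates agreeing, disjoint, and mixed chains", {
  x <- rnorm(500)
  expect_equal(gelman_rubin(list(x, x)), 1, tolerance = 1e-9)
  expect_identical(gelman_rubin(list(rep(0, 100), rep(1, 100))), Inf)
  expect_equal(gelman_rubin(list(rep(0.3, 50), rep(0.3, 50))), 1)
  set.seed(10)
  well_mixed <- lapply(1:4, function(i) rnorm(2000))
  expect_lt(gelman_rubin(well_mixed), 1.1)
  disjoint <- list(rnorm(2000, 0, 0.1), rnorm(2000, 5, 0.1))
  expect_gt(gelman_rubin(disjoint), 10)
  expect_error(gelman_rubin(list(x)), "2 chains")
  expect_error(gelman_rubin(list(1:5, 1:5)), "short")
  expect_error(gelman_rubin(list(rnorm(20), rnorm(30))), "equal length")
})

test_that("posterior_mode finds histogram peaks and respects ties", {
  # constant samples: mode within half a bin of the constant
  expect_lt(abs(posterior_mode(rep(0.3, 200), 0.01, interval = c(0, 1)) - 0.3),
            0.00501)
  set.seed(3)
  z <- rnorm(200000)
  expect_equal(posterior_mode(z, 0.05, interval = c(-5, 5)), 0,
               tolerance = 0.08)
  # bimodal with unequal masses: the heavier mode wins
  mix <- c(rnorm(30000, -2, 0.2), rnorm(70000, 2, 0.2))
  expect_equal(posterior_mode(mix, 0.1, interval = c(-5, 5)), 2,
               tolerance = 0.15)
  expect_error(posterior_mode(rnorm(50), 0.1), "100")
})

test_that("retained samples never leave the prior box", {
  ds <- generate_cue_dataset(generator_config(n = 120, seed = 8))
  priors <- prior_box()
  fit <- run_inversion(ds, priors = priors,
                       config = chain_config(n_chains = 2, n_iterations = 3000,
                                             burn_in = 500, seed = 2))
  for (ch in fit$chains) {
    s <- ch$samples
    expect_true(all(s[, "cue0"] > priors$cue0[1] & s[, "cue0"] < priors$cue0[2]))
    expect_true(all(s[, "m"] > priors$m[1] & s[, "m"] < priors$m[2]))
    expect_true(all(s[, "sigma"] > priors$sigma[1] & s[, "sigma"] < priors$sigma[2]))
  }
})

test_that("run_inversion is deterministic and validates its inputs", {
  ds <- generate_cue_dataset(generator_config(n = 80, seed = 21))
  cfg <- chain_config(n_chains = 2, n_iterations = 2000, burn_in = 400, seed = 5)
  f1 <- run_inversion(ds, config = cfg)
  f2 <- run_inversion(ds, config = cfg)
  expect_identical(f1$point_estimates, f2$point_estimates)
  expect_identical(f1$posterior_means, f2$posterior_means)
  expect_identical(f1$per_chain_acceptance, f2$per_chain_acceptance)
  expect_equal(f1$pooled_sample_count, 2 * (2000 - 400))
  expect_error(run_inversion(ds[1:5, ], config = cfg), ">= 10")
})

test_that("posterior means track the OLS fit with sigma fixed and flat priors", {
  ds <- generate_cue_dataset(generator_config(n = 300, seed = 13,
                                              substrate_offsets = NULL))
  fit <- run_inversion(ds, sigma_fixed = 0.2,
                       config = chain_config(n_chains = 3, n_iterations = 8000,
                                             burn_in = 1000, seed = 6))
  ols <- coef(lm(cue ~ I(incubation_temp - 20), data = ds))
  expect_equal(unname(fit$posterior_means["cue0"]), unname(ols[1]),
               tolerance = 0.01)
  expect_equal(unname(fit$posterior_means["m"]), unname(ols[2]),
               tolerance = 0.002)
})

test_that("parameter recovery: mean absolute error across seeds is small", {
  # n = 718 draws from the generating model, five replicate seeds
  errs <- t(vapply(1:5, function(s) {
    ds <- generate_cue_dataset(generator_config(n = 718, seed = 100 + s,
                                                substrate_offsets = NULL))
    fit <- run_inversion(ds, config = chain_config(n_chains = 2,
                                                   n_iterations = 6000,
                                                   burn_in = 1000,
                                                   seed = 200 + s))
    c(cue0 = abs(fit$point_estimates[["cue0"]] - 0.475),
      m = abs(fit$point_estimates[["m"]] - (-0.016)))
  }, numeric(2)))
  expect_lt(mean(errs[, "cue0"]), 0.02)
  expect_lt(mean(errs[, "m"]), 0.004)
})

test_that("a zero-slope boundary truth pushes m against the upper prior bound", {
  ds <- generate_cue_dataset(generator_config(n = 718, seed = 31, m_true = 0,
                                              substrate_offsets = NULL))
  fit <- run_inversion(ds, config = chain_config(n_chains = 2,
                                                 n_iterations = 6000,
                                                 burn_in = 1000, seed = 32))
  # the prior box closes at 0, so the estimate piles up near the bound
  expect_gt(fit$point_estimates[["m"]], -0.004)
  expect_gt(fit$credible_intervals["97.5%", "m"], -0.002)
})

test_that("constructor guards reject degenerate settings", {
  expect_error(prior_box(cue0 = c(1, 0)), "low < high")
  expect_error(chain_config(burn_in = 100, n_iterations = 100))
  expect_error(temperature_response_params(cue0 = 1.2, m = -0.01))
  expect_error(temperature_response_params(cue0 = 0.5, m = 0.2))
})
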