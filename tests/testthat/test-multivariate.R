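# Fixture: dataset whose CUE follows the full six-term surface exactly
# (plus optional noise), for recovery and oracle checks.
surface_dataset <- function(n, noise_sd = 0, seed = 1,
                            coefs = default_cue_coefficients()) {
  set.seed(seed)
  ds <- generate_cue_dataset(generator_config(n = n, seed = seed))
  inputs <- list(temp_minus_20 = ds$incubation_temp - 20,
                 glucose = glucose_indicator(ds),
                 latitude = ds$latitude, longitude = ds$longitude,
                 map = ds$map, ph = ds$ph)
  mu <- predict_cue_full(inputs, coefs)
  ds$cue <- mu + rnorm(n, 0, noise_sd)
  ds
}

test_that("univariate screens recover exact and null relationships", {
  ds <- tiny_dataset(seq(0.2, 0.8, length.out = 7))
  ds$latitude <- seq(0, 60, length.out = 7)       # perfectly linear
  out <- suppressWarnings(univariate_screen(ds, "latitude"))  # lm warns on R^2 = 1
  expect_equal(out$r_squared, 1)
  expect_equal(out$slope, 0.01)
  expect_equal(out$intercept, 0.2)

  set.seed(5)
  big <- tiny_dataset(runif(600, 0.1, 0.9))       # covariate independent of cue
  big$map <- runif(600, 100, 3000)
  nul <- univariate_screen(big, "map")
  expect_gt(nul$p_value, 0.05)
  expect_lt(abs(nul$slope), 1e-4)

  con <- tiny_dataset(c(0.2, 0.4, 0.6))
  expect_error(univariate_screen(con, "latitude"), "constant")
  expect_error(univariate_screen(con[1:2, ], "ph"), ">= 3")
})

test_that("stepwise recovers the generating surface within 2 SE", {
  truth <- default_cue_coefficients()
  ds <- surface_dataset(600, noise_sd = 0.02, seed = 23)
  fit <- stepwise_cue_fit(ds)
  expect_setequal(fit$retained,
                  c("temp_minus_20", "glucose", "latitude", "longitude",
                    "map", "ph"))
  co <- fit$coefficients
  for (i in seq_len(nrow(co))) {
    term <- sub("^\\(Intercept\\)$", "intercept", co$term[i])
    expect_lt(abs(co$estimate[i] - truth[[term]]), 2 * co$std_error[i] + 1e-12)
  }
  expect_gt(fit$r_squared, 0.9)
})

test_that("stepwise drops pure-noise covariates when temperature drives cue", {
  set.seed(31)
  n <- 500
  ds <- generate_cue_dataset(generator_config(n = n, seed = 31,
                                              substrate_offsets = NULL))
  # covariates scrambled: only temperature is informative
  for (col in c("latitude", "longitude", "map", "ph"))
    ds[[col]] <- sample(ds[[col]])
  fit <- stepwise_cue_fit(ds, criterion = "BIC")
  expect_true("temp_minus_20" %in% fit$retained)
  expect_lt(length(setdiff(fit$retained, "temp_minus_20")), 3)
})

test_that("degenerate constant indicator is dropped with a warning", {
  ds <- surface_dataset(200, noise_sd = 0.02, seed = 11)
  ds$substrate_category <- "glucose"              # indicator now constant
  expect_warning(fit <- stepwise_cue_fit(ds), "constant")
  expect_false("glucose" %in% fit$retained)
  expect_error(stepwise_cue_fit(ds[1:10, ]), "complete cases")
})

test_that("forcing all candidates reproduces the direct OLS fit", {
  ds <- surface_dataset(300, noise_sd = 0.05, seed = 41)
  fit <- stepwise_cue_fit(ds, selection = "backward", criterion = "AIC",
                          min_complete = 30)
  # oracle: plain multiple regression on the same frame
  ols <- lm(cue ~ temp_minus_20 + glucose + latitude + longitude + map + ph,
            data = fit$data)
  kept <- intersect(fit$retained, names(coef(ols)))
  sel_ols <- lm(reformulate(fit$retained, "cue"), data = fit$data)
  expect_equal(setNames(fit$coefficients$estimate, fit$coefficients$term),
               coef(sel_ols)[fit$coefficients$term], tolerance = 1e-12)
})

test_that("relative influence is symmetric, complete, and order-free", {
  set.seed(51)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)                  # independent, equal effects
  ds <- tiny_dataset(rep(0.5, n))
  ds$latitude <- x1; ds$longitude <- x2
  ds$cue <- 0.5 + 0.05 * x1 + 0.05 * x2 + rnorm(n, 0, 0.05)
  fit <- stepwise_cue_fit(ds, candidates = c("latitude", "longitude"))
  infl <- relative_influence(fit)
  expect_equal(sum(infl$influence$percent), 100, tolerance = 1e-9)
  expect_equal(infl$influence$percent,
               c(50, 50), tolerance = 6)           # symmetry up to MC noise

  # informative + noise predictor: the informative one dominates
  ds2 <- ds
  ds2$cue <- 0.5 + 0.08 * x1 + rnorm(n, 0, 0.03)
  fit2 <- stepwise_cue_fit(ds2, candidates = c("latitude", "longitude"),
                           selection = "backward")
  if (length(fit2$retained) >= 2) {
    infl2 <- relative_influence(fit2)
    expect_gt(infl2$influence$percent[infl2$influence$term == "latitude"], 95)
  }

  # single predictor: trivially 100%
  fit3 <- stepwise_cue_fit(ds, candidates = "latitude")
  infl3 <- relative_influence(fit3)
  expect_equal(infl3$influence$percent, 100)
})

test_that("relative influence equals a direct all-orderings average", {
  set.seed(61)
  n <- 300
  ds <- tiny_dataset(rep(0.5, n))
  ds$latitude <- rnorm(n); ds$longitude <- 0.6 * ds$latitude + rnorm(n)
  ds$ph <- runif(n, 4, 9)
  ds$cue <- 0.4 + 0.04 * ds$latitude + 0.02 * ds$longitude +
    0.01 * ds$ph + rnorm(n, 0, 0.05)
  fit <- stepwise_cue_fit(ds, candidates = c("latitude", "longitude", "ph"),
                          selection = "backward", min_complete = 30)
  preds <- fit$retained
  if (length(preds) >= 2) {
    infl <- relative_influence(fit)
    # oracle: enumerate orderings explicitly with sequential anova R^2 gains
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    r2 <- function(terms) if (length(terms) == 0) 0 else
      summary(lm(reformulate(terms, "cue"), data = fit$data))$r.squared
    gains <- setNames(numeric(length(preds)), preds)
    all_orders <- perms(preds)
    for (ord in all_orders)
      for (j in seq_along(ord))
        gains[ord[j]] <- gains[ord[j]] +
          (r2(ord[seq_len(j)]) - r2(ord[seq_len(j - 1)])) / length(all_orders)
    oracle_pct <- 100 * gains / sum(gains)
    got <- setNames(infl$influence$percent, infl$influence$term)
    expect_equal(got[names(oracle_pct)], oracle_pct, tolerance = 1e-8)
  }
})

test_that("the packaged full formula reproduces printed arithmetic", {
  base <- list(temp_minus_20 = 0, glucose = 0, latitude = 0, longitude = 0,
               map = 0, ph = 0)
  expect_equal(predict_cue_full(base), 0.319)
  base$glucose <- 1
  expect_equal(predict_cue_full(base), 0.491)
  base$glucose <- 0; base$ph <- 7
  expect_equal(predict_cue_full(base), 0.543)
  base$ph <- NULL
  expect_error(predict_cue_full(base), "ph")
})

test_that("a model fitted on noise-free data predicts the surface exactly", {
  ds <- surface_dataset(200, noise_sd = 0, seed = 71)
  fit <- suppressWarnings(stepwise_cue_fit(ds, selection = "backward"))  # exact fit
  newpt <- list(temp_minus_20 = 3, glucose = 1, latitude = -12,
                longitude = 100, map = 1500, ph = 5.5)
  truth <- predict_cue_full(newpt)
  coefs <- setNames(fit$coefficients$estimate,
                    sub("^\\(Intercept\\)$", "intercept", fit$coefficients$term))
  # terms dropped by selection on a noise-free fit have zero true weight
  pred <- coefs[["intercept"]] +
    sum(vapply(setdiff(names(coefs), "intercept"),
               function(tm) coefs[[tm]] * newpt[[tm]], numeric(1)))
  expect_equal(pred, truth, tolerance = 1e-8)
})

test_that("glucose/others split fits recover distinct intercepts", {
  set.seed(81)
  n <- 400
  ds <- generate_cue_dataset(generator_config(n = n, seed = 81,
                                              substrate_offsets = NULL,
                                              sigma_true = 0.1))
  glc <- glucose_indicator(ds) == 1
  # impose distinct reference intercepts on the two regimes
  ds$cue <- pmin(pmax(ifelse(glc, 0.491, 0.319) -
                        0.016 * (ds$incubation_temp - 20) +
                        rnorm(n, 0, 0.1), 0.002), 0.993)
  fits <- fit_by_substrate(ds, config = chain_config(n_chains = 2,
                                                     n_iterations = 5000,
                                                     burn_in = 1000, seed = 9))
  expect_lt(abs(fits$glucose$point_estimates[["cue0"]] - 0.491), 0.02)
  expect_lt(abs(fits$others$point_estimates[["cue0"]] - 0.319), 0.02)
  empty <- ds[glc, ]
  expect_error(fit_by_substrate(empty), "empty")
})
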