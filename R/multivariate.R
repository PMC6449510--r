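# Covariate analysis of CUE: univariate screens, stepwise multi-predictor
# regression with a glucose indicator, an order-independent relative-
# influence decomposition (averaged sequential sums of squares, LMG), and
# per-substrate temperature fits.

.glucose_categories <- c("glucose", "glucose_plus_N", "glucose_plus_C",
                         "glucose_plus_salt")

#' Glucose indicator from the substrate category
#'
#' 1 if the record's substrate category is any glucose variant (glucose,
#' glucose + N, glucose + C, glucose + salt), else 0; `NA` when the category
#' is missing.
#'
#' @param ds Observation data.frame with a `substrate_category` column.
#' @return Integer vector of 0/1/NA.
#' @export
glucose_indicator <- function(ds) {
  ifelse(is.na(ds$substrate_category), NA_integer_,
         as.integer(ds$substrate_category %in% .glucose_categories))
}

# assemble the multivariate model frame on the paper's predictor scale
.model_frame <- function(ds, candidates) {
  cols <- list(cue = ds$cue)
  for (cand in candidates) {
    cols[[cand]] <- switch(cand,
      temp_minus_20 = ds$incubation_temp - 20,
      glucose = glucose_indicator(ds),
      latitude = ds$latitude,
      longitude = ds$longitude,
      map = ds$map,
      ph = ds$ph,
      mat = ds$mat,
      cn_ratio = ds$cn_ratio,
      stop("unknown candidate predictor: ", cand))
  }
  df <- as.data.frame(cols)
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Univariate covariate screen
#'
#' Ordinary least-squares simple regression of CUE on a single covariate,
#' as used to screen site covariates (latitude, longitude, MAT, MAP, pH,
#' C/N) one at a time.
#'
#' @param ds Observation data.frame.
#' @param covariate Column name (`"latitude"`, `"map"`, ...) or one of the
#'   derived names `"temp_minus_20"` / `"glucose"`.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value` (slope test),
#'   `n`.
#' @export
univariate_screen <- function(ds, covariate) {
  df <- .model_frame(ds, covariate)
  if (nrow(df) < 3) stop("need >= 3 paired records; found ", nrow(df))
  x <- df[[covariate]]
  if (stats::var(x) == 0) stop("covariate '", covariate, "' is constant")
  fit <- stats::lm(cue ~ x, data = df)
  coefs <- summary(fit)$coefficients
  list(slope = unname(coefs["x", "Estimate"]),
       intercept = unname(coefs["(Intercept)", "Estimate"]),
       r_squared = summary(fit)$r.squared,
       p_value = if (nrow(df) > 2) unname(coefs["x", "Pr(>|t|)"]) else NA_real_,
       n = nrow(df))
}

#' Stepwise multi-predictor regression of CUE
#'
#' Stepwise model selection over the candidate predictors, with temperature
#' centered at 20 degC and the glucose indicator from [glucose_indicator()].
#' Complete-case analysis; constant candidate columns are dropped with a
#' warning before selection. Coefficients are returned on the same scale as
#' the packaged full formula (see [predict_cue_full()]).
#'
#' @param ds Observation data.frame.
#' @param candidates Predictor names; default the six-term set
#'   `temp_minus_20`, `glucose`, `latitude`, `longitude`, `map`, `ph`.
#' @param selection Stepwise direction: `"both"` (default), `"forward"`, or
#'   `"backward"`.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @param min_complete Minimum complete cases required; default 30.
#' @return Object of class `cue_model`: `coefficients` (data.frame term /
#'   estimate / std_error), `intercept`, `n_used`, `r_squared`, `retained`
#'   (predictor names kept), `lm` (the underlying fit), `criterion`,
#'   `selection`.
#' @export
stepwise_cue_fit <- function(ds,
                             candidates = c("temp_minus_20", "glucose",
                                            "latitude", "longitude", "map", "ph"),
                             selection = c("both", "forward", "backward"),
                             criterion = c("AIC", "BIC"),
                             min_complete = 30) {
  selection <- match.arg(selection)
  criterion <- match.arg(criterion)
  df <- .model_frame(ds, candidates)
  if (nrow(df) < min_complete)
    stop("insufficient complete cases for the multivariate fit: ", nrow(df),
         " < ", min_complete)
  constant <- candidates[vapply(candidates, function(p)
    stats::var(df[[p]]) == 0, logical(1))]
  if (length(constant) > 0) {
    warning("dropping constant predictor(s): ", paste(constant, collapse = ", "))
    candidates <- setdiff(candidates, constant)
    df <- df[, c("cue", candidates), drop = FALSE]
  }
  k <- if (criterion == "BIC") log(nrow(df)) else 2
  null_fit <- stats::lm(cue ~ 1, data = df)
  full_formula <- stats::reformulate(candidates, response = "cue")
  full_fit <- stats::lm(full_formula, data = df)
  start_fit <- if (selection == "forward") null_fit else full_fit
  sel <- stats::step(start_fit, scope = list(lower = ~1, upper = full_formula),
                     direction = selection, k = k, trace = 0)
  coefs <- summary(sel)$coefficients
  terms_kept <- setdiff(rownames(coefs), "(Intercept)")
  structure(list(
    coefficients = data.frame(term = rownames(coefs),
                              estimate = unname(coefs[, "Estimate"]),
                              std_error = unname(coefs[, "Std. Error"]),
                              stringsAsFactors = FALSE),
    intercept = unname(coefs["(Intercept)", "Estimate"]),
    n_used = nrow(df), r_squared = summary(sel)$r.squared,
    retained = terms_kept, lm = sel, data = df,
    criterion = criterion, selection = selection),
    class = "cue_model")
}

#' @export
print.cue_model <- function(x, ...) {
  cat("Stepwise CUE regression (", x$selection, ", ", x$criterion, "): n = ",
      x$n_used, ", R^2 = ", round(x$r_squared, 3), "\n", sep = "")
  print(transform(x$coefficients, estimate = signif(estimate, 4),
                  std_error = signif(std_error, 3)))
  invisible(x)
}

#' Relative influence of retained predictors
#'
#' Order-independent decomposition of the model's explained variance:
#' each predictor's share is its sequential sum-of-squares increment
#' averaged over all orderings of the retained predictors (the LMG
#' decomposition), computed exhaustively from all-subset R-squared values
#' and normalized to sum to 100%.
#'
#' @param model A `cue_model` from [stepwise_cue_fit()].
#' @param ds Ignored if the model carries its fitting data (the default);
#'   otherwise an observation data.frame to rebuild it from.
#' @return Object of class `cue_influence`: data.frame `influence` with
#'   columns `term` and `percent` (sums to 100), plus `method`. A
#'   single-predictor model returns 100% with a note.
#' @export
relative_influence <- function(model, ds = NULL) {
  stopifnot(inherits(model, "cue_model"))
  preds <- model$retained
  df <- model$data
  if (is.null(df)) df <- .model_frame(ds, preds)
  if (length(preds) == 0) stop("model retains no predictors")
  if (length(preds) == 1) {
    out <- data.frame(term = preds, percent = 100, stringsAsFactors = FALSE)
    return(structure(list(influence = out, method = "lmg",
                          note = "single predictor: trivially 100%"),
                     class = "cue_influence"))
  }
  p <- length(preds)
  # R^2 of every subset, keyed by a bitmask over preds
  r2 <- numeric(2^p)
  r2[1] <- 0
  for (mask in seq_len(2^p - 1)) {
    members <- preds[bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0]
    fit <- stats::lm(stats::reformulate(members, response = "cue"), data = df)
    r2[mask + 1] <- summary(fit)$r.squared
  }
  share <- stats::setNames(numeric(p), preds)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1, j - 1)
    incr_by_size <- vector("list", p)     # increments grouped by |S|
    for (mask in 0:(2^p - 1)) {
      if (bitwAnd(mask, bit_j) != 0) next
      size <- sum(bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0)
      incr <- r2[bitwOr(mask, bit_j) + 1] - r2[mask + 1]
      incr_by_size[[size + 1]] <- c(incr_by_size[[size + 1]], incr)
    }
    # average within each subset size, then across sizes: equal weight to
    # each ordering of the predictors
    share[j] <- mean(vapply(incr_by_size, mean, numeric(1)))
  }
  pct <- 100 * share / sum(share)
  out <- data.frame(term = preds, percent = unname(pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent), ]
  rownames(out) <- NULL
  structure(list(influence = out, method = "lmg"), class = "cue_influence")
}

#' @export
print.cue_influence <- function(x, ...) {
  cat("Relative influence (averaged sequential SS over all orderings):\n")
  print(transform(x$influence, percent = round(percent, 2)))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Temperature inversion split by substrate (glucose vs others)
#'
#' Runs the Bayesian temperature-response inversion independently on the
#' glucose-amended records (any glucose variant) and on all other
#' substrate-classified records, to compare the reference-temperature CUE
#' between the two substrate regimes.
#'
#' @param ds Observation data.frame with `substrate_category` populated.
#' @param priors,config,sigma_fixed,t0 Passed to [run_inversion()]. The
#'   master seed in `config` spawns one sub-seed per subset so the two
#'   inversions are independent but jointly reproducible.
#' @return List with elements `glucose` and `others`, each a
#'   `cue_posterior`.
#' @export
fit_by_substrate <- function(ds, priors = prior_box(), config = chain_config(),
                             sigma_fixed = NULL, t0 = 20) {
  has_cat <- !is.na(ds$substrate_category)
  is_glc <- has_cat & ds$substrate_category %in% .glucose_categories
  subsets <- list(glucose = ds[is_glc, , drop = FALSE],
                  others = ds[has_cat & !is_glc, , drop = FALSE])
  for (nm in names(subsets))
    if (nrow(subsets[[nm]]) == 0) stop("empty '", nm, "' subset")
  seeds <- if (is.null(config$seed)) list(NULL, NULL) else {
    set.seed(config$seed)
    as.list(sample.int(.Machine$integer.max - 1L, 2))
  }
  out <- lapply(seq_along(subsets), function(i) {
    cfg <- config
    cfg$seed <- seeds[[i]]
    run_inversion(subsets[[i]], priors = priors, config = cfg,
                  sigma_fixed = sigma_fixed, t0 = t0)
  })
  names(out) <- names(subsets)
  out
}

#' Packaged default coefficients of the full CUE formula
#'
#' The six-predictor linear formula relating CUE to incubation temperature
#' (centered at 20 degC), a glucose indicator, signed latitude and longitude
#' in degrees, mean annual precipitation (mm/yr), and soil pH. Shipped as
#' editable CSV under `extdata`.
#'
#' @return Named numeric vector of coefficients, including `intercept`.
#' @export
default_cue_coefficients <- function() {
  tab <- utils::read.csv(system.file("extdata", "default_cue_coefficients.csv",
                                     package = "soilcue", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$estimate, tab$term)
}

#' Predict CUE from the full multi-predictor formula
#'
#' Linear combination of the covariates under either a fitted `cue_model`
#' or the packaged default coefficients: intercept + temperature term +
#' glucose indicator + latitude + longitude + MAP + pH. Every covariate the
#' coefficient set uses must be supplied; a missing one is an error naming
#' it.
#'
#' @param inputs Named list or one-row data.frame of covariates on the
#'   predictor scale: `temp_minus_20`, `glucose` (0/1), `latitude`,
#'   `longitude`, `map`, `ph` (only those with nonzero coefficients are
#'   required).
#' @param coefficients A `cue_model`, a named numeric vector with an
#'   `intercept` element, or `NULL` (default) for the packaged defaults.
#' @return Predicted CUE (scalar, or vector if the inputs are vectors).
#' @export
#' @examples
#' predict_cue_full(list(temp_minus_20 = 0, glucose = 1, latitude = 0,
#'                       longitude = 0, map = 0, ph = 0))  # 0.491
predict_cue_full <- function(inputs, coefficients = NULL) {
  coefs <- if (is.null(coefficients)) default_cue_coefficients()
  else if (inherits(coefficients, "cue_model"))
    stats::setNames(coefficients$coefficients$estimate,
                    sub("^\\(Intercept\\)$", "intercept",
                        coefficients$coefficients$term))
  else coefficients
  terms <- setdiff(names(coefs), "intercept")
  missing_terms <- terms[!terms %in% names(inputs)]
  if (length(missing_terms) > 0)
    stop("missing covariate(s): ", paste(missing_terms, collapse = ", "))
  out <- coefs[["intercept"]]
  for (tm in terms) {
    v <- inputs[[tm]]
    if (any(is.na(v))) stop("missing covariate(s): ", tm)
    out <- out + coefs[[tm]] * v
  }
  unname(out)
}
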