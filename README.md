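# soilcue

Tools for global syntheses of **soil microbial carbon-use efficiency
(CUE)** — the fraction of carbon uptake that soil microbes allocate to
growth rather than respiration. CUE is a first-order parameter of
microbial-explicit soil-carbon models, but published measurements span
nearly the whole unit interval and depend strongly on incubation
temperature and carbon substrate. `soilcue` provides a tested,
reproducible pipeline for one-row-per-measurement literature compilations:

* **Data model & I/O** — a standard CSV schema for CUE observations with
  site coordinates, climate covariates (MAT, MAP), soil properties (pH,
  C/N), plant functional type, incubation temperature, and substrate
  descriptors; validation, group summaries and frequency tables
  (`read_cue_dataset()`, `validate_cue_dataset()`, `summarize_cue_by()`,
  `cue_histogram()`).
* **Conversion** — CUE from raw reported quantities via the three standard
  routes, in precedence order: `CUE = ΔMBC/ΔC_substrate`,
  `CUE = ΔMBC/(ΔMBC + R_cum)`, `CUE = ΔMBC/(ΔMBC + R·t)`
  (`derive_cue()`).
* **Temperature inversion** — Bayesian constraint of the linear response
  `CUE = CUE₀ + m(T − 20)` by five-chain Metropolis–Hastings sampling
  under box-uniform priors (CUE₀ ∈ (0,1), m ∈ (−0.1,0)), with
  Gelman–Rubin diagnostics and histogram-mode point estimates
  (`run_inversion()`).
* **Substrate analysis** — keyword classification of substrate text,
  degree-of-reduction (γS) lookup against a packaged 26-entry table,
  ANOVA + Tukey HSD group comparisons with compact letter displays, and
  nitrogen-addition effects (`classify_substrate()`, `gamma_s()`,
  `compare_cue_groups()`, `nitrogen_effect()`).
* **Multivariate regression** — univariate covariate screens, stepwise
  selection over {temperature, glucose indicator, latitude, longitude,
  MAP, pH}, LMG relative-influence decomposition, and split temperature
  fits for glucose vs other substrates (`stepwise_cue_fit()`,
  `relative_influence()`, `fit_by_substrate()`, `predict_cue_full()`).
* **Synthetic data** — a seeded generator emulating the statistical
  structure of a global compilation, so the whole pipeline is testable
  end-to-end (`generate_cue_dataset()`).

A thin command-line front end over these functions ships at
`inst/scripts/cue-pipeline.R` (subcommands `simulate`, `convert`,
`summarize`, `fit-temperature`, `substrate`, `regress`).

## Worked example

Generate a synthetic 718-record observation table drawn from the
temperature model `CUE = 0.475 − 0.016 (T − 20)` with noise SD 0.2, then
constrain the parameters by the five-chain inversion:

```r
library(soilcue)

ds  <- generate_cue_dataset(generator_config(n = 718, seed = 11,
                                             substrate_offsets = NULL))
fit <- run_inversion(ds, config = chain_config(seed = 1))
fit
#> CUE temperature-response inversion (5 chains, 718 observations)
#>   CUE = cue0 + m (T - 20)
#>          mode    mean ci_lower ci_upper r_hat
#> cue0   0.4625  0.4623   0.4454   0.4793     1
#> m     -0.0178 -0.0178  -0.0198  -0.0159     1
#> sigma  0.1933  0.1927   0.1830   0.2030     1
#>   pooled samples: 495000 | acceptance: 0.26 0.24 0.26 0.28 0.26
```

The histogram-mode estimates (`mode`) recover the generating values
CUE₀ = 0.475 and m = −0.016 within the posterior uncertainty: the 95%
credible intervals cover both, and R-hat = 1 for every parameter says the
five chains mixed to the same distribution. The estimated noise SD
(`sigma` ≈ 0.19) matches the generating 0.2.

Substrate structure on a table generated *with* group effects:

```r
ds2 <- generate_cue_dataset(generator_config(n = 718, seed = 11))
head(summarize_cue_by(ds2, "substrate_category"), 4)
#>            group   n      mean        sd
#> 1     amino_acid  90 0.6149593 0.2412391
#> 2        glucose 178 0.6653674 0.2091310
#> 3 glucose_plus_C  26 0.7639095 0.2094930
#> 4 glucose_plus_N  62 0.6493505 0.2228279

nitrogen_effect(ds2, "high_molecular")   # % change of mean CUE with N addition
#> [1] -45.2

classify_substrate("glucose + NH4NO3")
#> [1] "glucose_plus_N"
gamma_s("glucose")$gamma_s               # degree of reduction
#> [1] 4

# packaged six-predictor formula: glucose amendment at the 20 degC reference
predict_cue_full(list(temp_minus_20 = 0, glucose = 1, latitude = 0,
                      longitude = 0, map = 0, ph = 0))
#> [1] 0.491
```

See `vignettes/cue-methods.Rmd` for the model assumptions, sampler
design, and the generator's documented limitations.

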