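Package: soilcue
Title: Global Analysis of Soil Microbial Carbon-Use Efficiency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing literature measurements of soil microbial
    carbon-use efficiency (CUE): conversion of reported raw quantities
    (microbial biomass carbon accumulation, substrate consumption, cumulative
    or rate-based respiration) to CUE, Bayesian constraint of the linear
    temperature-response parameters by multi-chain Metropolis-Hastings
    sampling with Gelman-Rubin convergence diagnostics, substrate-type
    classification with a degree-of-reduction lookup table, group comparisons
    (one-way ANOVA, Tukey HSD, compact letter display), stepwise
    multi-predictor regression with an order-independent relative-influence
    decomposition, and a seeded synthetic-data generator emulating the
    structure of a global observation compilation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
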