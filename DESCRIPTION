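Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event
    Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A pharmacovigilance analysis pipeline for spontaneous
    adverse-event reporting systems in the style of FAERS. Reads
    FAERS-like quarterly report tables, deduplicates cases, selects
    primary-suspect drug exposures against a configurable set of MedDRA
    preferred terms, and screens drug-event pairs with four
    disproportionality algorithms (reporting odds ratio, proportional
    reporting ratio, the Bayesian confidence propagation neural network
    information component, and the multi-item gamma Poisson shrinker)
    combined under a joint signal criterion. Includes demographic
    stratification, Weibull time-to-onset modelling with failure-type
    classification, descriptive characteristic tables, and a synthetic
    reporting-system generator with analytically known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
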