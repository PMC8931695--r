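Package: phenoact
Title: Latent Phenotyping and Neural Coactivation Analysis for the Stop
    Signal Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for latent-variable analysis of cognitive-control
    phenotypes and task-based neuroimaging measures. Provides latent class
    analysis of binary symptom items with information-criterion and
    likelihood-ratio class enumeration (including the parametric bootstrap),
    exploratory and confirmatory factor analysis of region-level task
    activation ("neural coactivation networks") with standard fit indices,
    multi-group measurement-invariance testing and latent-mean contrasts,
    stop-signal behavioural quality control and integration-method SSRT,
    region-level linear mixed models with site random intercepts, and a
    synthetic-data generator that emulates the joint structure of all inputs
    so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans,
    car,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
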