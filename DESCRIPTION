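Package: scitseq
Title: Sequential Models for Adherence and Symptom-Score Forecasting in
    Subcutaneous Immunotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal modelling of patient adherence and
    symptom/medication scores during multi-year subcutaneous allergen
    immunotherapy (SCIT). Provides a sequential latent-variable state-space
    model with variational filtering inference, an autoregressive LSTM
    baseline, one-step and multi-step (rollout) forecasting protocols with
    cross-validated metrics, counterfactual treatment-contrast simulation,
    integrated-gradients feature attribution for static covariates, a
    seeded synthetic-cohort generator with ground-truth severity paths for
    recovery experiments, and descriptive cohort statistics including
    withdrawal-reason contingency tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    jsonlite,
    withr,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
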