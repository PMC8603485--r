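Package: adherepilot
Title: Group-Sequential Design and Bayesian Adherence Analysis for a Two-Arm Pilot Trial
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for a two-stage group-sequential pilot
    randomized trial of medication adherence: Hwang-Shih-DeCani error-spending
    boundary computation with binding futility via recursive numerical
    integration, quantile substitution to t-scale boundaries, operating
    characteristics by Monte-Carlo simulation, derivation of pill-count and
    MEMS electronic-monitoring adherence endpoints with intention-to-treat
    imputation, a synthetic trial-data generator with known ground truth, and
    Bayesian random-intercept linear mixed models on logit-transformed
    adherence under weakly-informative or informative priors.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
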