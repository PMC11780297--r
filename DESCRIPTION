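Package: hftrialkit
Title: Tools for mHealth Heart-Failure Self-Care Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computational machinery for patient-centered mobile-health
    heart-failure trials: scoring and classification of self-care
    patient-reported-outcome instruments (SCHFI-style 0-100 standardized
    subscales, knowledge tests, KCCQ-12), a tailored text-message rule
    engine with weekly scheduling, Pocock-Simon biased-coin minimization
    randomization, wearable and connected-device adherence and activity
    metrics (wear time, valid days, blood-pressure categories, weight
    alerts), the trial statistics layer (change scores, pooled-SD Cohen's
    d with t-based confidence intervals, multiple imputation with Rubin
    pooling, random-intercept linear mixed models, feasibility metrics),
    and a synthetic-cohort generator with embedded ground truth so the
    whole pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
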