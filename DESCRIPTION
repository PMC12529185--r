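Package: trialemulate
Title: Target Trial Emulation for Sustained Medication Exposures with
    Longitudinal TMLE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for emulating head-to-head target trials of medication
    classes from pharmacy-dispensing and electronic-health-record style
    tables. Builds new-user cohorts with washout and eligibility flows,
    converts dispensings to exposure episodes under a coverage-and-gap rule,
    assembles discrete-time (30-day) person-interval datasets with
    missingness-indicator covariate encoding, fits super-learner propensity
    ensembles and LASSO outcome regressions, and estimates counterfactual
    cumulative incidence by unadjusted and inverse-probability-weighted
    product-limit estimators and by longitudinal targeted minimum loss-based
    estimation (TMLE) with influence-curve standard errors. Includes
    per-protocol and intention-to-treat protocols, risk-difference, average
    risk-difference, number-needed-to-treat and hazard-ratio contrasts,
    subgroup and effect-modification analyses, weight-truncation and
    g-value sensitivity analyses, and a synthetic EHR generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
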