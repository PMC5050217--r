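Package: burncohort
Title: Infection Hypersusceptibility Analysis for Severe Burn Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for analysing hypersusceptibility to repeated
    infections after severe burn trauma. Tabulates independent infection
    episodes from raw infection records with a waiting-list decision tree,
    computes standard burn severity scores (Baux, revised Baux, ABSI, Ryan),
    derives the plasma TNF-alpha/IL-10 cytokine ratio, and evaluates the
    ratio alone and combined with clinical scores as a predictor of three or
    more infection episodes using Firth-penalized logistic regression,
    stratified-bootstrap AUROC confidence intervals and Wilson score
    intervals with continuity correction. Includes a synthetic-cohort
    generator moment-matched to published group summaries so every stage is
    testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
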