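Package: d50als
Title: D50 Disease Progression Modelling and CSF Biomarker Analysis for ALS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the D50 sigmoidal disease-progression model to longitudinal
    ALSFRS-R scores of patients with amyotrophic lateral sclerosis, deriving
    the half-functionality time D50, the decline time constant dx, the relative
    disease course rD50, disease phases and aggressiveness strata. Implements
    the accompanying biomarker analysis pipeline for cerebrospinal-fluid
    neurofilament light chain (NfL): ROC curves with Youden-index cutoffs,
    analysis of covariance with estimated marginal means and Bonferroni post
    hocs, correlation and log-log regression, Mann-Whitney comparisons, and
    Kaplan-Meier survival with log-rank tests. A synthetic cohort generator
    reproduces the statistical structure of a cross-sectional ALS biomarker
    study (sigmoidal functional decline with rater noise, D50-dx coupling,
    sampling shift, a log-linear NfL model, censored survival) so that every
    stage of the pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    car,
    emmeans,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
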