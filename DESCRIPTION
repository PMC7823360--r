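Package: adews
Title: Early-Warning Risk Stratification for Alzheimer's Disease from
    Plasma Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building a regression-tree early-warning system for
    Alzheimer's disease (AD) risk from longitudinal plasma-biomarker cohorts.
    Implements a deviance-based binary regression tree for a dichotomous
    outcome with cost-complexity pruning and ten-fold cross-validated
    subtree selection; a rolling-window procedure that trains on an
    expanding window of visits and forecasts conversion at the next visit
    out of sample, with small-scale augmentation of the first training
    window and stratified-bootstrap confidence intervals; terminal-node
    risk-zone stratification with agreement statistics against clinical
    diagnosis; A/T classification of cerebrospinal-fluid profiles by
    published amyloid and phosphorylated-tau cutoffs; linear mixed-effects
    biomarker trajectory models; ROC analysis with stratified bootstrap and
    the DeLong test; multiple-regression power and sample-size calculations
    on the noncentral F distribution; and a synthetic longitudinal cohort
    generator emulating the statistical structure such analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC,
    optparse
Config/testthat/edition: 3
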