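Package: pdsubtype
Title: Data-Driven Subtyping of Parkinson's Disease from Motor and
    Non-Motor Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Standardized k-means subtyping of de novo Parkinson's disease
    patients from a 22-variable baseline table of motor and non-motor
    clinical scores. Provides min-max normalization with persisted rescaling
    parameters, restart-controlled Lloyd k-means with Calinski-Harabasz
    pseudo-F model selection over a range of cluster numbers, semantic
    subtype labelling by composite symptom severity, a nearest-centroid
    rule for classifying new patients, post-hoc subtype characterization
    (Hedges' g standardized mean differences with bootstrap confidence
    intervals, Wilcoxon rank-sum tests under family-wise Bonferroni
    thresholds, Pearson correlations), longitudinal motor and cognitive
    progression rates with an age-adjusted ANCOVA, and a moment-matched
    synthetic cohort generator that emulates the statistical structure of
    the PPMI baseline and follow-up tables for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
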