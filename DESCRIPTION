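Package: haploscore
Title: Scoring and Filtering Identical-by-Descent Segments with HaploScore
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identity-by-descent (IBD) segments reported by fast diplotype-based
    detectors such as GERMLINE contain many false positives, especially below 4 cM,
    because permissive diplotype matching tolerates arbitrary haplotype phase switches.
    This package implements HaploScore, a dynamic-programming metric that scores a
    candidate segment by the minimum number of genotyping errors and haplotype switch
    errors needed to reconcile it as a single-haplotype match, weighted by the inverse
    error rates and normalised by segment site count. It also provides trio-based
    validation of candidate segments via Mendelian transmission, estimators for the
    switch and genotyping error rates, score-threshold-matrix generation and filtering,
    ROC/precision-recall evaluation, genetic-map coordinate handling, readers and
    writers for GERMLINE match files and phased genotype formats, and a synthetic
    trio-cohort simulator with planted ground truth so the whole pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
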