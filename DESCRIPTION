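Package: dosagescreen
Title: Screening for Dosage-Sensitive Genes from Time-Course, Cross-Study,
    Single-Cell and Chromatin-Occupancy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage screen for genes whose expression tracks the dosage
    of a regulatory protein. Implements dynamic Spearman correlation of gene
    fold-changes against a protein trajectory from a perturbation time-course,
    loss-of-function-intolerance (pLI) filtering, a cross-study
    differential-expression replication tally, cell-type-resolved correlation
    from single-cell counts with a marker-based excitatory/inhibitory neuron
    split, spike-in-calibrated window quantification of CUT&RUN fragment data
    with a negative-binomial Wald test for differential occupancy, and the
    closed-form auxiliary estimators (optical-fractionator stereology and
    delta-delta-Ct relative expression). A seeded synthetic-data module
    generates every pipeline input with planted ground truth so the whole
    screen is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
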