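Package: mircortex
Title: Covariate-Adjusted Association and Integrated miRNA-mRNA Pathway
    Analysis for Cortical Non-Coding RNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for relating cortical non-coding RNA
    (Nanostring nCounter miRNA and RNA-seq lincRNA) to Alzheimer's disease
    neuropathology. Implements probe-background adjustment, call-rate and
    low-expression filtering, quantile normalization and empirical-Bayes
    batch adjustment; per-feature linear-model association with neuritic
    plaque burden, neurofibrillary tangle burden and pathologic AD adjusted
    for age, sex, study, neuronal proportion, post-mortem interval and RNA
    integrity; confounder-aware network construction via a pathology F-test
    screen and forward-stepwise BIC edge selection; and integrated
    miRNA-target-pathway scoring combining gene-level evidence by Stouffer's
    method with a chi-square product joint statistic, including mediation-style
    effect decomposition. A synthetic cohort generator with planted ground
    truth makes every stage testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    sva,
    BiocParallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
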