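Package: saltGRN
Title: Consensus Gene Regulatory Network Inference for Condition-Specific
    Regulator Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate upstream transcription factors of a target
    gene from condition-dependent expression data. Implements a candidate
    funnel (empirical-Bayes moderated differential expression, set overlap
    with one-hybrid hits and known regulators), per-target stochastic
    gradient-boosted tree network inference with impurity-based edge
    importances, replicate consensus-frequency ranking under
    condition-specific thresholds, and integration with promoter binding
    evidence. Includes a simulator that generates time-course expression
    from a ground-truth regulatory network for benchmarking regulator
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    limma,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'boost.R'
    'consensus.R'
    'deg.R'
    'funnel.R'
    'infer.R'
    'io.R'
    'pipeline.R'
    'report.R'
    'saltGRN-package.R'
    'simulate.R'
    'utils.R'
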