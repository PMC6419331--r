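Package: promi
Title: Multiple Imputation and Moderated Linear Models for Peptide-Centric
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A peptide-centric differential-abundance pipeline for label-free
    quantitative proteomics, aimed at post-translational modification (PTM)
    data such as reversible cysteine oxidation. Parses peptide-measurement
    exports from label-free quantitation software, applies score and
    contaminant filtering, parsimony-based accession resolution and
    identifier consolidation; imputes missing values by drawing from normal
    distributions with robustly estimated parameters, distinguishing
    missing-at-random cells (feature/condition mean) from left-censored
    missing-not-at-random cells (lower Tukey fence of the pooled intensity
    distribution); fits per-feature linear models (ordinary or Huber-robust
    least squares) with empirical-Bayes variance moderation and
    false-discovery-rate control; aggregates calls across multiple
    imputations with a right-tailed exact binomial test; and benchmarks
    decision methods with ROC operating points on spike-in designs with
    known ground truth, for which a synthetic spike-in generator is
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'decide.R'
    'diffexpr.R'
    'evaluate.R'
    'impute.R'
    'pipeline.R'
    'preprocess.R'
    'promi-package.R'
    'synth.R'
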