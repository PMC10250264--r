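Package: flankrel
Title: Reliability of Flanker-Style Difference Scores from Trial-Level
    Reaction Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how reliably two-condition reaction-time
    tasks measure individual differences, with the arrow flanker task as
    the canonical case. Implements trial-level scoring with the standard
    exclusion rules (100 ms floor, per-individual 3*MAD slow-tail cut,
    accuracy criterion), test-retest reliability via the single-measure
    absolute-agreement intraclass correlation ICC(A,1) and Pearson
    correlation, permutated and Monte Carlo split-half resampling with
    Spearman-Brown adjustment, trial-subsampling reliability curves fit
    against a grid of Spearman-Brown prophecy curves, Fisher-z comparison
    of independent correlations with the matching power analysis, a
    leave-two-out leverage analysis for outlier participants, and a
    trial-level synthetic data generator with closed-form true-score
    reliability for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
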