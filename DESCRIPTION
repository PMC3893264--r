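Package: adarv
Title: Adaptive Combination of P-Values for Rare-Variant Association Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant association testing for case-control
    studies by adaptive combination of per-site P-values (ADA).  Per-variant
    evidence is summarised by two-sided mid-P Fisher exact tests on allele
    counts, weighted by a Madsen-Browning control-frequency weight, truncated
    at a grid of candidate P-value thresholds, and accumulated separately over
    deleterious-inclined and protective-inclined sites; significance is
    assessed by a two-layer phenotype-permutation procedure that adjusts for
    the adaptive threshold search.  The package also provides the classical
    burden comparators (weighted Fisher combination of mid-P values, fixed
    1%/5% MAF-threshold collapsing, weighted-sum rank test, variable-threshold
    test) under a shared permutation engine, a coalescent-style haplotype-pool
    simulator with a population-attributable-risk disease model, and harnesses
    for type-I-error and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
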