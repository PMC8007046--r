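Package: mpdiverge
Title: Simulating and Quantifying Genomic Divergence Between Paired Primary and Metastatic Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-cell three-dimensional lattice simulation of primary tumor
    growth with passenger and driver variant accrual, monoclonal metastatic
    seeding, and paired metastasis growth; reconstruction of single-cell
    genealogies and the tree-based elements of metastatic-primary divergence
    (detectable ancestors, most recent detectable ancestor, pre-dissemination
    branch lengths); virtual multi-region sampling and sequencing with
    negative-binomial depth noise, pooled variant allele frequencies and
    Hudson-style Fst; a closed-form branching-process model of the expected
    pre-dissemination divergence as a function of seeding time, detectability
    and growth mode; and statistics over per-seeding-event divergence series
    (heteroscedasticity, zigzag and valley segmentation, subclone-expansion
    co-occurrence permutation tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    data.table,
    jsonlite,
    lmtest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
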