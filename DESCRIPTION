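Package: cooccurphylo
Title: Phylogeny-Aware Co-Occurrence Analysis of Binary Genome Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Detects positive and negative evolutionary associations between
    two families of binary genome traits (for example CRISPR-Cas subtypes and
    DNA double-strand-break repair components). Implements a phylogeny-naive
    screen (phi coefficients against frequency-matched control genes, a
    one-sided delta-phi t-test, Fisher exact tests with Bonferroni
    correction), a phylogenetically corrected correlated-evolution test
    (maximum-likelihood fits of independent versus dependent two-trait Markov
    models via Felsenstein pruning, likelihood-ratio test, bootstrap-tree
    median decision rule), and single-linkage clustering of the resulting
    signed association matrix. A synthetic-data module simulates Yule trees
    and trait evolution under both models so the whole pipeline is testable
    without genome databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
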