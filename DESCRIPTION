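Package: slowfast
Title: Site-Rate Partitioning and Bipartition Recovery for Slow-Fast
    Phylogenetic Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Audits the "slow-fast" alignment-trimming practice in deep
    phylogenetics. Simulates amino-acid alignments on random trees under
    reversible substitution models with discrete-gamma rate heterogeneity,
    assigns sites to substitution rate categories by empirical Bayes under a
    fixed tree, builds rate-specific alignment partitions by tandem
    replication, reconstructs bootstrap tree samples per partition with an
    ML-distance neighbor-joining estimator, and quantifies how recovery of
    reference bipartitions depends on site rate and branch length
    (Robinson-Foulds distances, support thresholds, rank correlations,
    tree-space ordination, compositional bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
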