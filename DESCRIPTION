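Package: sigreverse
Title: Multilevel Expression-Change Analysis and Signature-Reversal Drug
    Repurposing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for calling multilevel expression changes between
    two sample groups (e.g. tumour versus adjacent normal tissue) from bulk
    RNA-seq read counts, and for repurposing drugs whose perturbation
    signatures reverse the disease signature.  Stages include PCA and
    dendrogram sample quality control, negative-binomial differential
    expression with median-of-ratios normalisation, weighted coexpression
    network construction with topological-overlap module detection run
    separately per group, Fisher-z differential gene correlation between
    groups, hypergeometric over-representation analysis against GMT gene-set
    collections, and direction-reversed Fisher exact matching of drug
    perturbation signatures with a coverage filter.  A seeded synthetic-data
    generator plants every structure the downstream stages assume
    (differentially expressed genes, correlated modules with group-specific
    disruption, outlier samples, a reversing drug) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2,
    optparse
Config/testthat/edition: 3
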