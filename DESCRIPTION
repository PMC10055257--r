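Package: scqtl
Title: Cell-Type-Resolved Pseudo-Bulk eQTL Mapping with Multivariate Shrinkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for cell-type-resolved expression
    quantitative trait locus (eQTL) mapping from single-cell RNA-seq.
    Aggregates single-cell counts into per-donor pseudo-bulk profiles per
    cell type, maps cis-eQTL and genotype-by-disease interaction eQTL with
    a two-random-effect linear mixed model (kinship and aggregated-cell-count
    weights), jointly shrinks effect estimates across cell types with an
    empirical-Bayes mixture of multivariate normals yielding local false
    sign rates, classifies eQTL by sharing and specificity, colocalizes
    eQTL with GWAS summary statistics via approximate Bayes factors, and
    tests enrichment against distance-matched null variant sets. Includes
    a synthetic-data generator with planted effects for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    vcfR,
    withr,
    Rcpp,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
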