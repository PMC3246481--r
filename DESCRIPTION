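Package: pathperm
Title: Pathway-Based SNP-Set Association Testing by Within-Cluster Permutation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control pathway (SNP-set) association testing for stratified
    genome-wide association panels. Provides per-SNP quality control (call
    rate, exact Hardy-Weinberg test, cross-cluster allele-frequency
    heterogeneity), additive-model logistic association with cluster
    adjustment, max-SNP gene scoring over flanked and merged gene regions,
    SUMSTAT and SUMSQ set statistics with empirical p-values from
    within-cluster case-control label permutation, random-gene-set type-I
    calibration, an LD-pruned mean-p set test, and a synthetic stratified
    genotype generator so the whole pipeline can be exercised end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
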