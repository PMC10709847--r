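Package: methhier
Title: Hierarchical Classification of Primary Tumor Type from DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a two-layer hierarchical classifier of primary cancer type
    from Illumina 450K DNA-methylation beta values. A class taxonomy is derived
    by UPGMA clustering of per-subtype mean methylomes under Pearson
    correlation distance, with the number of groups chosen by the silhouette
    coefficient. Group- and type-specific CpG markers are screened by a
    three-stage cascade: one-way ANOVA, Tukey-Kramer one-vs-all-others
    comparison with an adaptive delta-beta relaxation schedule, and Boruta
    shadow-feature confirmation. A random forest is trained per classification
    problem (one first-layer forest over groups, one second-layer forest per
    multi-type group) and predictions are emitted as ranked top-k-squared
    candidate sets. Includes a synthetic cohort generator with a planted group
    hierarchy, planted marker CpGs, beta-distributed noise, batch shifts and
    missingness, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    ranger,
    ape,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
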