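Package: epiqmdr
Title: SNP-SNP Interaction Discovery for Quantitative Traits with QMDR
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering pairwise SNP-SNP
    interactions (epistasis) associated with a quantitative trait such as
    body mass index. Provides genotype input from PLINK ped/map, VCF or
    plain dosage matrices; cohort quality control (call rate, exact
    Hardy-Weinberg test, minor allele frequency, linkage-disequilibrium
    pruning, pi-hat relatedness); covariate residualization of the trait;
    main-effect and knowledge-based candidate filtering; an exhaustive
    cross-validated Quantitative Multifactor Dimensionality Reduction
    (QMDR) pair search; pooled permutation significance with Bonferroni
    correction; an explicit (main-effect-preserving) permutation test of
    epistasis; nested-model variance-explained comparison; and a seeded
    synthetic-data generator for two-locus quantitative-trait models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
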