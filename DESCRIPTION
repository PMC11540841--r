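Package: karyopop
Title: Population Structure and Inversion Karyotype Analysis for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing diploid biallelic SNP-panel genotypes in
    structured marine populations, with emphasis on detecting and
    characterising putative chromosomal inversions. Provides Genepop and
    tabular genotype input/output, locus and individual quality control,
    candidate-SNP filtering from variant tables, per-sample diversity
    statistics with exact Hardy-Weinberg tests, pairwise linkage
    disequilibrium and the multilocus index of association, Weir-Cockerham
    F-statistics and hierarchical AMOVA with permutation tests, PCA and DAPC
    ordination, PCA-loading based driver-locus discovery, karyotype (AA/AB/BB)
    classification with the 1-0.5-0 diagnostic-frequency signature, EM
    haplotype-frequency estimation, admixture-model clustering via a Gibbs
    sampler with Evanno delta-K and Puechmaille K-selection, migrant
    detection, and a fully parameterised synthetic-data generator with ground
    truth for validating every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
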