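Package: dualnet
Title: Dual Local-Global Stacked Ensemble for SNP Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes disease-associated single-nucleotide polymorphisms
    (SNPs) from a regional case-control genotype matrix by combining two
    complementary performance scores: a local score from out-of-fold stacking
    ensembles trained on nonoverlapping 100-SNP genomic windows, and a global
    score from the same ensembles trained on functional-annotation-defined SNP
    groups. The two scores are blended by a weighting parameter selected with
    nested stratified cross-validation, SNPs are ranked, and top/bottom panels
    are evaluated by AUC with fold-wise confidence intervals. Includes genotype
    quality control (call rate, exact Hardy-Weinberg test, minor allele
    frequency, genotype-quality/read-depth masking), k-nearest-neighbour
    genotype imputation, linkage-disequilibrium proxy ablation, cross-cohort
    rank transfer, conventional baselines with paired tests, and a seeded
    synthetic-data generator with LD-block genotypes and planted causal
    variants for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ranger,
    glmnet,
    nnet,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
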