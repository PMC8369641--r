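Package: pearGS
Title: GWAS and Genomic Selection for Sugar Traits in Japanese Pear Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, association mapping and genomic prediction for
    fruit-sugar traits in multi-family pear breeding material. Provides a
    synthetic-population generator that emulates a cultivar collection plus
    F1 full-sib families with sugar-conversion QTL genetics, VCF/TSV
    genotype and phenotype input with marker quality control, VanRaden
    kinship, linkage-disequilibrium decay, tag-SNP selection, LD pruning and
    PCA, single-marker mixed-linear-model GWAS with a polygenic background
    (EMMA-style REML, P3D), a variational-Bayes BayesB multiple-QTL model
    with per-SNP inclusion probabilities and family effects, per-SNP and
    per-family variance-explained summaries, and GBLUP / vBayesB genomic
    prediction evaluated by leave-one-family-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
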