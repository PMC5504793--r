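Package: treegs
Title: Genomic Prediction and Association Mapping for Forest Tree
    Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-genome prediction and genome-wide association tools for
    open-pollinated tree breeding trials genotyped with SNP arrays. Provides
    genotype quality control (call-rate and minor-allele-frequency filters,
    mean imputation, windowed LD pruning), pairwise linkage disequilibrium
    with kinship- and structure-corrected variants and Hill-Weir decay
    fitting, LD-based effective population size with parametric confidence
    intervals, pedigree and genomic (VanRaden, Powell) relationship matrices,
    REML mixed models (ABLUP/GBLUP), ridge-regression BLUP marker effects,
    five Bayesian whole-genome regressions (Bayesian ridge, Bayes A, Bayes B,
    Bayes C-pi, Bayesian lasso) via a compiled Gibbs sampler, cross-validated
    predictive ability under SNP-subsetting and relatedness-controlled
    splits, and single-SNP association scans with and without a polygenic
    term. A forward Wright-Fisher simulator of half-sib breeding populations
    with substructure and block-design phenotypes supplies ground-truth test
    beds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
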