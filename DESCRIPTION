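Package: qgomics
Title: Quantitative Genetics, GWAS and Transcriptome Integration for
    Multi-Environment Variety Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for replicated multi-environment variety
    trials genotyped with SNP arrays and profiled by RNA-seq.  Implements
    ANOVA-based estimation of variance components, coefficients of
    variation, broad-sense heritability and genetic advance; SNP quality
    control, polymorphism information content, linkage-disequilibrium
    statistics with Hill-Weir decay fitting and Gabriel confidence-interval
    haplotype blocks; VanRaden kinship and principal components; single-
    marker association under fixed-effect (GLM) and mixed (MLM, P3D/EMMAX)
    models with stability and pleiotropy screens and allele-effect Tukey
    groupings; candidate-gene extraction in LD-decay windows around lead
    SNPs; FPKM-based differential-expression calling and hypergeometric
    category enrichment; and integration of association intervals with
    differentially expressed genes.  A synthetic-data module generates
    genotypes, phenotypes and expression counts with known truth so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
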