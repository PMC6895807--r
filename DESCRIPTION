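Package: gwasregions
Title: Two-Cohort Mixed-Model GWAS with Meta-Analysis and LD-Aware Region
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end post-GWAS analysis pipeline for two-cohort
    (two-breed) genetic association studies of quantitative and binary
    metabolic traits. Provides phenotype normalization and mixed-model
    covariate adjustment, genotype quality control with an exact
    Hardy-Weinberg test, an EMMAX-style spectral linear mixed-model
    association scan with GRM correction and effective-test-count
    Bonferroni thresholds, cross-cohort fixed-effects and
    heterogeneity-under-the-alternative (RE2) random-effects
    meta-analysis, clumping of suggestive SNPs into regions with
    fixed-size and linkage-disequilibrium-bound boundaries, tiered region
    prioritization, positional candidate-gene annotation from GFF3, and a
    block-LD two-cohort phenotype/genotype simulator with planted causal
    variants for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    GenomicRanges,
    IRanges,
    lme4,
    S4Vectors,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
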