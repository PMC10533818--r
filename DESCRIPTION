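Package: mqtlrisk
Title: Methylation-at-mQTL Risk Indices and Combined Polygenic Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and applies risk indices built from DNA methylation at
    methylation quantitative trait loci (mQTL CpGs), computes SNP polygenic
    risk scores from effect-allele dosages, and combines both into
    median-split risk groups with exact median-unbiased (mid-p conditional)
    odds ratios. Includes an exact Hardy-Weinberg equilibrium test and
    genotype QC filters, a permutation null over random CpG subsets for
    index specificity, surrogate-tissue variability summaries stratified by
    immune cell fraction, ROC/AUC evaluation utilities, and a synthetic
    cohort generator emulating genotype-coupled methylation with covariate,
    disease, and cell-type-mixture effects.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
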