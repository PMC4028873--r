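Package: cismeqtl
Title: Cross-Cohort cis-meQTL Mapping, Overlap, and Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping methylation quantitative trait loci (meQTLs) in
    cis: quality control of genotype and methylation-array data, linear
    regression of CpG methylation beta-values on allele counts within a 50 kb
    window with Holm (step-down Bonferroni) family-wise error control,
    cross-cohort overlap tables with log-space Fisher exact tests, sign
    concordance of association t-statistics with Poisson-binomial chance
    expectations, LD pruning, hierarchical clustering of t-statistics, and
    MAF-binned resampling tests for enrichment of meQTLs in arbitrary SNP
    target sets. Includes a multi-cohort synthetic-data generator that
    emulates ancestry-dependent allele frequency and linkage-disequilibrium
    structure, planted cis effects, batch effects, PCA-detectable outliers,
    and detection-p missingness, so every pipeline stage can be exercised and
    calibrated without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
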