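Package: egfrewas
Title: Multi-Cohort Epigenome-Wide Association Analysis of Kidney Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) of estimated
    glomerular filtration rate (eGFR) across multi-ethnic cohorts: per-cohort
    robust linear models of eGFR on DNA methylation beta values with
    heteroscedasticity-consistent (sandwich) or family random-intercept
    estimators, fixed-effect inverse-variance meta-analysis with FDR discovery
    and Bonferroni/direction-concordance replication calls, tissue-specific
    open-chromatin overlap enrichment with annotation-matched background
    resampling, cis-meQTL scanning on M-values, and empirical overlap tests
    linking GWAS SNPs, meQTL target CpGs, and EWAS signals. A synthetic-cohort
    generator with planted effects, CKD-EPI derived phenotypes, family
    structure, genotypes, and DNase hotspot fixtures makes the full pipeline
    testable without access to any consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    sandwich,
    lme4,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
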