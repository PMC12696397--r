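Package: chloy
Title: Clonal Hematopoiesis and Loss of Y Chromosome Co-Occurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing clonal hematopoiesis (CH)
    against mosaic loss of the Y chromosome (LOY) in FACS-sorted leukocyte
    fractions. Designates variants as germline or post-zygotic by cross-fraction
    presence within a subject, applies the staged variant filter cascade
    (caller prefilter, flag, gnomAD popmax, consequence, category-specific
    quality thresholds, singleton rule), categorises variants into myeloid,
    lymphoid and unknown driver classes, quantifies per-fraction LOY from
    mLRR-Y or droplet digital PCR measurements, and computes the stratified
    co-occurrence statistics (Fisher's exact tests, age-adjusted logistic
    regression odds ratios, Mann-Whitney VAF comparisons, Spearman burden
    correlations, Benjamini-Hochberg adjustment). A seeded synthetic cohort
    generator with full truth labels makes every stage testable without
    access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
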