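Package: popenrich
Title: Population-Specific Allele-Frequency Enrichment, IBD Sharing, and
    Replication Analysis for Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of admixed cohorts:
    scoring population-specific allele-frequency enrichment with a log2
    frequency-ratio statistic, filtering and merging pairwise
    identity-by-descent (IBD) segments into population sharing matrices and
    dendrograms, variant and sample quality control (Hardy-Weinberg exact
    test, LD pruning, PCA, outlier detection, cluster assignment, F_ST,
    kinship), covariate-adjusted genome-wide association scans with
    inverse rank-normal transformed phenotypes, and a Bonferroni-thresholded
    replication procedure against external association catalogues with
    greedy LD clumping. A Balding-Nichols cohort simulator with full ground
    truth makes every stage testable end-to-end without access to
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
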