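Package: sleepewas
Title: Epigenome-Wide Association Analysis of Sleep Initiation Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for epigenome-wide association studies
    (EWAS) of sleep initiation in cohort data with reduced-representation
    bisulfite sequencing (RRBS) methylation calls. Implements clock-time
    arithmetic for bedtime, sleep onset latency and sleep onset time
    measured by self-report, actigraphy and polysomnography; coverage and
    sample-availability filtering of CpG sites; per-site multivariable
    linear regression of each sleep measure on methylation level adjusted
    for age, sex, race, BMI percentile and batch, with Benjamini-Hochberg
    false discovery rate control; annotation of CpG sites onto genes with
    extended borders (-1500 bp upstream, +500 bp downstream); gene-set
    enrichment by hypergeometric and permutation tests and gene ontology
    over-representation. A seeded synthetic-data generator produces
    cohorts, gene models and beta-binomial methylation call sets with
    planted effects so every stage is testable without cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
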