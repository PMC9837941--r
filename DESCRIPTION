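Package: relapsedelta
Title: Paired Primary-Relapse Tumor Transcriptome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for matched primary-relapse tumor transcriptome
    cohorts, built around medulloblastoma-style study designs. Implements a
    pair-variance statistic (Euclidean distance between a patient's primary and
    relapse samples in top principal-component space of highly variable genes),
    pair-blocked empirical-Bayes moderated differential expression,
    signature-based cell-type deconvolution of bulk profiles with paired
    composition shift tests, rank-based single-sample enrichment scoring,
    expression-cutoff survival scanning with Bonferroni control, metagene
    construction, Cox models, and SNV fingerprint identity checks. A synthetic
    paired-cohort generator reproduces the statistical structure these methods
    assume, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
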