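Package: priorank
Title: Prioritizing Candidate Cancer Genes for Targeted Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks genes for targeted resequencing of cancer genomes using four
    per-gene prioritization signals: fitSNP differential expression ratio (DER)
    values, variance of logged expression, expression-copy-number dosage
    sensitivity (Spearman rank correlation), and frequency of copy-number loss
    derived from segmented profiles. Single and pairwise-combined rankings are
    evaluated by positive predictive value (PPV, the mutation rate among
    top-ranked genes) against the baseline mutation rate of a sequencing
    screen, with mutation-yield curves and PPV-by-score-cutoff curves.
    Strategies are compared across cohorts by weighted Spearman footrule rank
    aggregation (exhaustive or cross-entropy search). A seeded synthetic-cohort
    generator emulates all required inputs (gene annotation, expression matrix,
    SEG copy-number profiles, DER table, mutation screen) with tunable
    association between mutation status and each signal, so the full pipeline
    runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
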