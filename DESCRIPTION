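Package: famscan
Title: Gene-Family Somatic Mutation Burden and Survival Combination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether a gene family carries somatic mutations in
    excess of the cohort background while accounting for gene size, to scan
    combinations of family genes for association of mutation status with
    overall survival against a mutation-count-matched bootstrap null with
    empirical q-values, and to compare somatic and germline protein-position
    distributions. Includes a synthetic tumor-cohort generator (MAF-style
    mutation tables, clinical survival tables, expression summaries) with
    planted survival effects for calibration and power studies, plus
    from-first-principles Kaplan-Meier, log-rank, and Cox proportional
    hazards implementations with oracle-testable contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
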