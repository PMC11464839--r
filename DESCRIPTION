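Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance signal detection on
    FAERS-style spontaneous adverse-event report databases: ingest of linked
    multi-table report files, MedDRA preferred-term case definitions,
    report-type and drug-role filtering, drug-name normalization, descriptive
    summaries, and 2x2 contingency-based disproportionality statistics
    (reporting odds ratio, proportional reporting ratio, chi-squared) with
    configurable signal criteria and ranking. Includes a latent-cell inversion
    validator that recovers the unprinted cells of published 2x2 tables from
    (a, ROR, PRR, N) and checks internal consistency, and a synthetic
    report generator with known ground truth so every stage is testable
    without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
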