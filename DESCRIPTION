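Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for FAERS-style
    spontaneous reporting data: ingestion of quarterly '$'-delimited tables
    (DEMO, DRUG, REAC, THER) with case-version deduplication and
    primary-suspect drug filtering, MedDRA preferred-term to system-organ-class
    aggregation, 2x2 contingency construction, four signal-detection
    algorithms (reporting odds ratio, proportional reporting ratio, the
    Bayesian confidence propagation neural network information component, and
    the closed-form empirical Bayes geometric mean) combined under a
    conservative consensus rule, sex-stratified log-ROR matrices with
    hierarchical clustering order, and time-to-onset analysis. Includes a
    ground-truthed synthetic spontaneous-reporting database generator with
    planted drug-event associations so the whole pipeline is testable without
    access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    withr,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
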