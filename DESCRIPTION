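Package: mirscreen
Title: Functional miRNA Screen Scoring, Consensus Target Prediction and
    Signature Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for nominating tumor-suppressor
    microRNAs from reverse phase protein array (RPPA) mimic-screen readouts
    and following them through to patient outcomes. Scores each miRNA by the
    coefficient of variation and the Pearson correlation of its protein
    readout profile against an oncogene/tumor-suppressor class vector,
    classifies miRNAs as oncomiRs or tumor suppressors, filters per-database
    miRNA target predictions with database-specific score rules, forms
    multi-database consensus target sets, and evaluates a combined
    target-network z-score signature against survival with Kaplan-Meier
    curves and log-rank tests. Includes synthetic-data generators emulating
    the statistical structure of screen, prediction-database, cohort and
    qPCR inputs, plus delta-delta-Ct and RTCA quantification utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
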