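Package: cx3score
Title: Dynamic Blood Biomarker Scoring and TCR Repertoire Analytics for
    Checkpoint Inhibitor Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating on-treatment dynamics of the CX3CR1+ fraction
    of circulating CD8+ T cells as a blood-based biomarker of response to
    immune checkpoint inhibitor therapy. Computes the CX3CR1 score (maximal
    percent change from baseline by a landmark week) with its >= 20 percent
    decision rule, full diagnostic evaluation (confusion-table metrics with
    Jeffreys intervals, Woolf odds-ratio intervals, Fisher's exact test,
    empirical and logistic ROC with DeLong AUC intervals, Youden optimal
    cut-points), Kaplan-Meier / log-rank / Mantel-Haenszel survival comparison
    of score-defined groups, and T-cell receptor repertoire analytics
    (productive filtering, clonality as one minus Pielou evenness,
    Morisita-Horn overlap, Gini index and Lorenz curves, PAM10 global CDR3
    alignment distances, UPGMA dendrograms, shared-clonotype counting).
    Includes seeded synthetic generators for clinical cohorts and clonally
    expanded repertoires so every stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
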