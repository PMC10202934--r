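Package: oncomir
Title: MicroRNA Prioritization, Reporter-Assay Quantification and Spatial
    Co-Expression Analysis for Oral Cancer Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying microRNA-driven silencing of the CDK2AP1
    (DOC1) tumor suppressor in oral squamous cell carcinoma. Implements a
    miRNA prioritization score combining expression-quantile grouping with
    miRNA-target interaction-evidence tiers, quantification of qPCR
    (delta-delta-Ct) and dual-luciferase reporter assays including the
    Coefficient of Drug Interaction for miR-combination experiments, a
    cell-level tissue-microarray pipeline (outlier exclusion, tumor-core
    summaries, anti-correlation ranking, miR-21 stratification, digital
    core reconstruction), a tumor-only somatic variant filter cascade with
    copy-number gain/loss classification, and Kaplan-Meier/log-rank
    survival stratification by immunohistochemistry thresholds and one- or
    two-marker expression splits. Seeded synthetic-data generators emulate
    every input type with known ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
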