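Package: waitlineCEA
Title: Cost-Utility Analysis of Breast-Screening Waiting-List Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic pipeline for comparing organizational
    strategies that shorten the waiting list of a breast-radiology
    screening service. Couples a tumor-kinetics model (exponential growth
    between the mammographic detection and palpability thresholds) with a
    Poisson metastasis-probability model, a hospital cost ledger (daily
    costs, revenues, margins, multi-year projections), quality-adjusted
    life-year (QALY) accounting, and incremental cost-effectiveness ratio
    (ICER) ranking. Includes a seeded synthetic-cohort generator emulating
    a TNM-staged patient registry so the full pipeline is testable without
    patient-level data, and a YAML-configured orchestration layer that
    emits CSV tables and a Markdown report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
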