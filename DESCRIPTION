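Package: prcea
Title: Cost-Effectiveness Microsimulation of Pulmonary Rehabilitation After
    COPD Hospitalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov microsimulation comparing pulmonary rehabilitation (PR)
    started within 90 days of a hospitalization for chronic obstructive
    pulmonary disease (COPD) against no PR, from both societal and health
    system perspectives. Provides a registry of probability, utility and
    cost parameters with uncertainty distributions fitted from published
    summary statistics, a synthetic-cohort generator emulating the Medicare
    study population, a patient-level lifetime simulation engine with
    life-table based post-year-1 mortality and excess-mortality calibration,
    cost accounting with QALY discounting and incremental cost-effectiveness
    comparison, probabilistic and one-way sensitivity analyses, scenario
    analyses, and threshold search on the cost per PR session.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
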