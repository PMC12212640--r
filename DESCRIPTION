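Package: clincohort
Title: Clinical-Genomic Cohort Definition and Autonomous Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic, offline analysis engine for integrated
    clinical-genomic tables. Provides a three-part dataset bundle format
    (README, attribute index, tab-delimited data table), a structured
    filter grammar for cohort definition with strict left-to-right
    evaluation, automatic statistical test selection by variable kind,
    case-control enrichment via odds-ratio tests, Kaplan-Meier and Cox
    proportional-hazards survival comparison, global association scans
    with false-discovery-rate control, a rule-based natural-language
    intent front-end with a validated adapter contract for external
    language models, and a synthetic-cohort generator with plantable
    odds-ratio and hazard-ratio effects for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
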