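Package: cvdcds
Title: Guideline Rules Engine for Community Cardiovascular Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A clinical decision support rules engine for 10-year
    cardiovascular disease (CVD) risk assessment and management in
    primary-care screening programmes. Assesses categorical 10-year CVD
    risk from WHO/ISH-style risk chart lookups (with automatic fallback
    to a cholesterol-free chart when lipids are unavailable), applies
    guideline rules for clinically-high-risk classification, risk
    underestimation flags, blood-pressure-lowering, statin and
    antiplatelet indications, and treatment targets. Ships a
    dual-implementation validation harness (engine versus an
    independently coded decision-table oracle), a reproducible synthetic
    cohort generator with a deterministic rule-boundary test suite, and
    care-cascade analytics for the screening to referral to treatment to
    adherence pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
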