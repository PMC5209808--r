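Package: priogap
Title: Weighted Multi-Criteria Prioritisation and Control-Tool Gap Analysis for Animal Diseases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A configurable scoring and ranking engine for multi-criteria
    prioritisation of infectious animal diseases and gap analysis of disease
    control tools (diagnostics, vaccines, pharmaceuticals). Implements a closed
    weighted scoring system in which every criterion is normalised to a maximum
    weighted total of 100 via the coefficient W = 100/(X*I), expert-panel
    aggregation to consensus score sheets with dissent (knowledge-gap)
    recording, overall, per-category and per-criterion competition rankings,
    re-weighting sensitivity analysis with Kendall tau-b rank concordance, and
    a seeded synthetic-study generator for parameter-recovery testing. Ships
    the reference tables of a published 52-disease EU prioritisation exercise
    as validated fixtures, plus CSV/JSON readers and writers and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
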