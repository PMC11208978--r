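Package: raCEA
Title: Cost-Effectiveness of Treatment Sequences in Rheumatoid Arthritis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A lifetime multistate Markov cohort model for the
    cost-effectiveness of rheumatoid arthritis treatment sequences
    initiated with biosimilar infliximab, biosimilar adalimumab, or
    leflunomide after inadequate response to methotrexate. Disease
    progression is tracked on the Health Assessment Questionnaire
    Disability Index (HAQ-DI), with ACR-response-based switching,
    per-cycle discontinuation, HAQ-adjusted mortality, and a terminal
    supportive-care state. Provides base-case incremental
    cost-effectiveness ratios, probabilistic sensitivity analysis with
    Dirichlet-beta-gamma sampling and cost-effectiveness acceptability
    curves, one-way deterministic sensitivity (tornado) analysis, a
    scenario grid, and a synthetic-data module generating a
    Gompertz-Makeham life table and later-line parameter tables so the
    full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
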