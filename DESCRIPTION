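Package: mentsr
Title: Modified MeNTS Surgical Prioritization Scoring and Reliability Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A configurable scoring engine for the modified Medically
    Necessary Time-Sensitive (MeNTS) surgical prioritization instrument:
    sixteen 1-5 scored factors across Procedure, Disease and Patient
    components (total range 16-80, lower = higher surgical priority),
    shipped as an editable rubric document with full exhaustiveness and
    exclusivity validation. Includes queue ranking with deterministic
    tie-breaking, cohort score summaries and tier crosswalks, an
    inter-rater reliability engine (two-way random-effects ANOVA
    intraclass correlation for absolute agreement with Cicchetti
    interpretation bands and a tolerance-based rank-consistency
    statistic), and a seeded synthetic gynecologic-surgery cohort
    generator with a controllable rater-noise model so the full
    score-rank-reliability pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
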