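Package: imscore
Title: Immunoscore Scoring and Outcome Analysis for Neoadjuvant-Treated
    Muscle-Invasive Bladder Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CD3+/CD8+ T-cell densities in tumor-center and
    invasive-margin regions, converts densities to cohort percentiles, derives
    Immunoscore (IS-0 to IS-4) and biopsy-adapted (ISb-0 to ISb-2) categories at
    maximally selected log-rank cut-offs, and relates the scores to pathologic
    complete response (exact 2x2 and Freeman-Halton RxC contingency tests) and to
    time-to-recurrence and overall survival (Kaplan-Meier, center-stratified Cox,
    restricted mean survival time, Wald chi-squared importance shares, Schoenfeld
    event sizing). Includes a seeded synthetic-cohort and synthetic-slide
    generator so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    withr
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
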