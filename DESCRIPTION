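Package: tpptriage
Title: Target Product Profile Triage for Medicine Development Pipelines
Version: 0.1.0
Authors@R:
    person("AIM", "Pipeline Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens a registry of candidate medicines through ordered
    eligibility criteria, rates survivors against nine critical
    target-product-profile (TPP) parameters with dual-rater adjudication,
    converts ordinal ratings into weighted scores and phase-specific
    high/medium/low potential tiers, and renders traffic-light matrices and
    landscape summary tables. Ships seeded synthetic-data generators and
    fixtures transcribing a published preterm-birth pipeline landscape so
    the whole workflow is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
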