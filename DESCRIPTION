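Package: preglith
Title: Drug Discontinuation in Pregnancy from Primary-Care Prescribing Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for drug-utilisation studies of medication discontinuation
    around pregnancy using longitudinal primary-care prescribing records.
    Implements pregnancy cohort derivation with registration-based
    eligibility, gap-based prescribing-episode construction with a refill-gap
    rule, the continuous-prescribing predicate and last-prescription rule,
    prevalence of prescribing by calendar period, an age-band-matched
    non-pregnant comparator group built from simulated index dates,
    Kaplan-Meier estimation of time to last prescription with gestational
    censoring, characteristics tables with logit-transform binomial
    confidence intervals, and a seeded synthetic electronic-health-record
    generator so the whole pipeline is testable without access to any
    proprietary database. The worked application is lithium prescribing
    before and during pregnancy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
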