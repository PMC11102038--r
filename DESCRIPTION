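Package: adrquant
Title: Quantitative Severity Grading and Frequency Estimation for
    Adverse Drug Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative characterization of adverse drug reactions (ADRs)
    from spontaneous adverse-event reports and person-weighted prescription
    survey records. Implements reporting odds ratio (ROR) disproportionality
    screening with Woolf confidence intervals, a penalized outcome-weighted
    severity score with analytically derived five-grade boundaries, an
    underreporting-corrected ADR frequency estimator keyed to annual
    prescription volumes, consistency evaluation against expert grade tables,
    and odds-ratio screening of drug-ADR-target associations, including
    fatal-risk target discovery. Ships a seeded simulator of FAERS-like
    report collections and MEPS-like prescription records so the full
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
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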