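Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    spontaneous adverse-event case reports in the style of the Australian
    Database of Adverse Event Notifications (DAEN) public export. Reads
    case-level report CSVs and summary count tables, recodes adverse-event
    terms against Standardized MedDRA Query (SMQ) style term sets at narrow or
    broad scope, builds 2x2 contingency tables under full-database and
    active-comparator designs (with subgroup, single-suspected and annual
    restrictions), and computes reporting odds ratios (ROR) and proportional
    reporting ratios (PRR) with Woolf-type confidence intervals and a
    minimum-case signal rule. Includes a synthetic report simulator with
    plantable reporting odds ratios so every stage of the pipeline can be
    exercised and validated without access to a live pharmacovigilance
    database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
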