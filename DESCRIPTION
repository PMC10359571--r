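Package: lynchledger
Title: Amalgamation, Linkage and Coverage Estimation for Germline
    Mismatch-Repair Laboratory Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a national patient-level resource of germline
    mismatch-repair (MMR) gene testing records from heterogeneous laboratory
    extracts. Provides a synthetic-data generator with known ground truth,
    keyed pseudonymisation of patient identifiers (NHS number, date of birth
    and postcode), harmonisation of structured and free-text laboratory
    dialects into a common data model with HGVS variant extraction and
    syntactic validation, collapsing of per-gene results into 365-day test
    episodes with a result-severity hierarchy, deterministic linkage to an
    ICD-10 coded cancer registry, and imputation of total historic national
    testing activity from inflated laboratory audit counts, including
    carrier-yield estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    openssl,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
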