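Package: cpzequiv
Title: Chlorpromazine-Equivalent Dose Conversion for Antipsychotic
    Prescription Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cleans antipsychotic dispensing claims and converts them to
    total chlorpromazine-equivalent daily doses at therapy initiation and
    follow-up timepoints, stratified by administration route.  Implements
    route-specific repair rules for the day's-supply and quantity fields
    (refill-interval checks for oral and rectal forms, minimum dosing
    intervals for long-acting injectables, cost-based quantity repair for
    short-acting injectables), a new-user cohort builder with washout and
    refill requirements, lookback-window exposure assessment, stratified
    summaries, and a seeded synthetic claims generator with ground truth
    for validating every pipeline stage without access to restricted
    administrative data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
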