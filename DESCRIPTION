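Package: triageval
Title: Evaluation of Major-Incident Triage Tools Against
    Intervention-Based Reference Standards
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Encodes eleven major-incident primary triage algorithms (among
    them the BCD Triage Sieve, CareFlight, JumpSTART, START, MIMMS, MPTT,
    MPTT-24, MSTART, NARU, RAMP and the Paediatric Triage Tape) as
    declarative ordered-check decision rules, assigns intervention-based
    reference triage categories from timed life-saving interventions
    (Lerner's criteria with paediatric fluid-resuscitation extensions), and
    measures each tool's accuracy in predicting Priority 1 status:
    sensitivity, specificity, under- and over-triage, single-operating-point
    trapezoidal AUC with Wilson continuity-corrected and DeLong intervals,
    stratified by age subgroup. Includes a synthetic paediatric trauma
    registry generator so the full pipeline is testable without access to
    confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
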