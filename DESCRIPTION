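Package: rxpeer
Title: Peer Networks and Physician Adoption of New Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study peer influence on physician adoption of newly
    marketed drugs. Builds four physician peer networks (patient-sharing,
    medical group, hospital, and training) from claims-like record tables,
    classifies adopters with a median prescribing rule, estimates
    linear-in-means peer effects by two-stage least squares with peer-mean
    instruments (including weak-instrument and overidentification
    diagnostics), and computes a Bonacich-type social multiplier for
    intervention targeting. A synthetic-cohort generator with a known
    structural adoption process makes every stage testable without
    proprietary data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    methods,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
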