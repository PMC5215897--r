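Package: polydem
Title: Nested Case-Control Analysis of Polypharmacy and Dementia in Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for nested case-control studies of
    polypharmacy and incident dementia in longitudinal health-insurance claims
    data. Covers incident-case selection with washout, 1:1 matching on age,
    sex, income level and diagnosis year, look-back exposure derivation
    (average daily prescribed drug count, per-class medication possession
    ratios for potentially inappropriate medications, Charlson comorbidity
    index), odds-ratio estimation by unconditional and conditional logistic
    regression, likelihood-ratio interaction screens, comorbidity-subgroup
    analyses with fixed-effect inverse-variance pooling, and a synthetic
    claims generator with known-truth effect sizes so the whole pipeline is
    testable without access to real insurance data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
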