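Package: ardsrecog
Title: Estimating Clinician Recognition of ARDS from Ventilator Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how often clinicians recognise the acute respiratory
    distress syndrome (ARDS) in mechanically ventilated patients, using only
    discrete variables available in electronic health records: height, gender,
    delivered tidal volumes, and ARDS documentation flags. The package derives
    predicted body weight and the lowest standardized tidal volume for each
    patient, screens clinical factors with standardized-coefficient regressions
    under Bonferroni control, fits kernel-density naive Bayes models to the
    documented and control subgroups, classifies non-documented ARDS patients
    as recognized or unrecognized from the equal-posterior boundary in the
    (height z-score, tidal volume) plane, and reports recognition rates by
    hypoxemia severity with bootstrap confidence bands. A seeded synthetic
    cohort generator emulating the default-tidal-volume clinician heuristic
    supports end-to-end testing without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
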