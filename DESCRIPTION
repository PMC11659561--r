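Package: drdscreen
Title: Diagnostic Accuracy, Equity and Bias Analysis for Paired-Eye
    Retinal Screening Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for paired-eye diagnostic-accuracy
    non-inferiority trials of autonomous diabetic retinal disease (DRD)
    screening systems. Provides ETDRS-scale case-definition rules, eye- and
    participant-level confusion tables with diagnosability and worst-case
    imputation of insufficient-quality results, participant-clustered
    bootstrap inference with disease-spectrum expansion and one-sided
    non-inferiority tests, design power simulation, Population Achieved
    Sensitivity (PAS) equity metrics with break-even adoption ratios,
    subgroup and intersectional bias audits, and a seeded synthetic trial
    generator calibrated to published marginal distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
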