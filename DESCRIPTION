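Package: snapdx
Title: Diagnostic Accuracy of Sensory Nerve Action Potentials for
    Diabetic Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate sensory nerve action potential (SNAP)
    amplitudes as diagnostic tests for clinical diabetic neuropathy.
    Classifies participants into control, diabetes-without-neuropathy and
    diabetic-neuropathy groups from Utah Early Neuropathy Scale and
    Michigan Neuropathy Screening Instrument scores; computes
    single-nerve amplitude cutoffs, the sural-to-radial amplitude ratio
    and the combined polyneuropathy sensory index (CPNSI); and derives
    age-stratified sensitivity, specificity, predictive values and
    dichotomous-test ROC areas with exact Clopper-Pearson and
    DeLong-variance confidence intervals. Includes a seeded
    zero-inflated log-normal cohort simulator calibrated to published
    normative amplitude ranges, plus descriptive range tables and
    group-comparison tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
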