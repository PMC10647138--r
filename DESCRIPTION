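Package: whtrcut
Title: Optimal Waist-to-Height-Ratio Cut-Offs for Pediatric Cardiometabolic Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and validates waist-to-height-ratio (WHtR) cut-offs that
    discriminate children and adolescents (ages 6-18) with clustered
    cardiometabolic risk factors (high blood pressure, high triglycerides,
    low HDL cholesterol, high fasting glucose) under IDF or modified NCEP
    pediatric metabolic-syndrome component definitions. Implements
    weight-status subsampling against pluggable growth references, sex- and
    age-specific WHtR percentile estimation on a low-risk reference
    subsample, ROC-based evaluation of percentile-indexed and static
    candidate cut-offs (AUC, sensitivity, specificity, Youden index),
    consolidation of per-stratum optima into proposed static cut-offs, and
    external validation via classifier metrics and covariate-adjusted
    logistic-regression odds ratios. Ships a seeded synthetic multi-region
    cohort generator with a planted WHtR-risk threshold so the whole
    pipeline is testable end to end, including cut-off recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
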