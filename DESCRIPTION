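Package: obsbmd
Title: Oxidative Balance Score and Bone Mineral Density Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the association between the oxidative balance
    score (OBS) and bone mineral density (BMD) in children and adolescents
    using NHANES-style cohort tables. Implements OBS construction from 16
    dietary nutrients and 4 lifestyle components with gender-stratified
    tertile scoring, sequential cohort exclusions, baseline descriptive
    comparisons with automatic test selection, Gaussian generalized linear
    model association analysis with leave-one-covariate-out sensitivity,
    age-interaction and subgroup analysis, generalized additive model
    dose-response curves with two-segment threshold (breakpoint) regression
    and likelihood-ratio testing, and product-of-coefficients mediation
    through oxidative-stress biomarkers with bootstrap inference. Includes a
    seeded synthetic cohort generator that emulates the relevant statistical
    structure (age-dependent sign reversal, U-shaped dose-response, partial
    mediation) for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    foreign,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
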