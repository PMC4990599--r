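Package: romaP
Title: Age-Stratified ROMA Ovarian Cancer Risk Scoring and Diagnostic
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the Risk of Ovarian Malignancy Algorithm (ROMA)
    combining serum HE4 and CA125 through a logistic predictive index, in
    two variants: the standard form with separate pre- and post-menopausal
    coefficient sets, and an age-stratified form ("ROMA P") that replaces
    the menopausal dichotomy with eight age-interval coefficient sets
    obtained by stepwise linear reduction between the youngest- and
    oldest-stratum coefficients, scored against a single population-wide
    cutoff. Ships the diagnostic-evaluation machinery needed to assess
    such scores: confusion-matrix metrics, empirical ROC curves,
    trapezoidal AUC, DeLong variance and paired AUC comparison,
    Youden-index cutoff selection, and the Mann-Whitney U test, together
    with a seeded synthetic-cohort generator emulating the age and marker
    structure of a gynecological referral population, CSV input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
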