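Package: foodGRS
Title: Food-Specific Genetic Risk Scores and Gene-Diet Interaction Screening for Childhood BMI
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how food consumption modulates polygenic
    susceptibility to obesity in children. Computes unweighted and weighted
    genetic risk scores (GRS) over a SNP panel with PLINK-style per-non-missing
    averaging, recodes food-frequency-questionnaire ratings to weekly
    consumption and dietary summary indices, derives LMS-based BMI-for-age
    z-scores, and runs a two-level gene-diet interaction screening cascade:
    whole-GRS x food interaction tests (with a dichotomized-score fallback for
    borderline signals), per-SNP screens with a direction-consistency filter,
    construction and validation of food-specific risk scores, stratified effect
    estimation in low/high genetic-risk groups, and shared-SNP set analysis.
    Includes a synthetic-cohort generator with configurable true main and
    interaction effects for power, calibration, and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
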