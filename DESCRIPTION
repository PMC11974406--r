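Package: densitraj
Title: Longitudinal Consistency of Paired BI-RADS Breast-Density Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the longitudinal consistency of ordinal
    BI-RADS breast-density assessments recorded by two paired raters (an AI
    density model and interpreting radiologists) over repeated screening
    examinations. Classifies each woman's ordered density sequence into one
    of four longitudinal patterns (constant, ascending, descending,
    bi-directional) in both four-category and binary (dense vs non-dense)
    contexts, compares raters with McNemar paired-proportion tests and
    Stuart-Maxwell marginal-homogeneity tests, stratifies the analysis over
    clinically motivated subgroups (post-menopausal age, stable image-based
    BMI, same radiologist, fellowship-trained radiologists), fits an
    image-based BMI proxy, and ships a seeded synthetic-cohort simulator
    with a latent-density misclassification model so the whole pipeline runs
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    jsonlite,
    ggplot2,
    generics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
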