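Package: glimcrp
Title: CRP-Based GLIM Inflammation Criteria for ICU Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nutritional-assessment analysis pipeline for critically ill
    patients: derives the maximum C-reactive protein (CRP) level over the
    first three ICU days as a GLIM (Global Leadership Initiative on
    Malnutrition) etiologic inflammation criterion, combines it with the
    age-dependent GLIM low-BMI phenotypic criteria, and evaluates the
    resulting four-group classification against a composite outcome of
    in-hospital death, Barthel index < 60 at discharge, and length of stay
    of 14 days or more. Includes ICU claims-cohort eligibility filtering,
    ICD-10 diagnosis categorisation, a modified SOFA score and catecholamine
    index, linear interpolation of missing CRP trajectories, ROC/AUC analysis
    with Youden-index cut-off selection per diagnosis subgroup, Kruskal-Wallis
    and Conover-Iman rank tests across groups, and a synthetic claims-cohort
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
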