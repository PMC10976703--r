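Package: fdgvoi
Title: Individual-Level FDG-PET VOI Analysis of MCI-to-Dementia Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for individual-level
    FDG-PET volume-of-interest (VOI) assessment of conversion from mild
    cognitive impairment (MCI) to dementia. Generates synthetic cohorts
    (regional SUVr profiles, conversion intervals, longitudinal MMSE/CASI
    trajectories), renders labeled 3D PET phantoms, computes
    pons-referenced standard uptake value ratios (SUVr), builds a control
    normative database, Z-transforms regional uptake, calls regional
    hypometabolism at Z < -2, evaluates conversion-prediction rules
    (sensitivity, specificity, predictive values with exact binomial
    confidence intervals), and fits marginal (GEE-style) longitudinal
    models of cognitive decline with robust standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
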