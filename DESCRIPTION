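Package: mmgru
Title: Multi-Modal Recurrent Networks for Predicting MCI-to-AD Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conversion from mild cognitive impairment (MCI) to
    Alzheimer's disease (AD) from irregular-length longitudinal biomarkers.
    One gated recurrent unit (GRU) encoder per data modality (cognitive
    scores, CSF analytes, demographics, MRI phenotypes) turns each
    variable-length visit sequence into a fixed-size representation; the
    representations are concatenated and classified with an l1-regularised
    logistic head. Encoders are pre-trained on cognitively normal and AD
    subjects before MCI converter/non-converter labels are introduced.
    Includes exact backpropagation-through-time gradients, a seeded
    synthetic-cohort simulator with latent severity trajectories and block
    modality missingness, and a horizon-windowed repeated stratified
    cross-validation protocol with accuracy, sensitivity, specificity and
    AUC summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils,
    withr
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
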