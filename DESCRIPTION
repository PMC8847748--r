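Package: cogconvert
Title: Longitudinal Cognitive-Conversion Prediction and Treatment-Reassignment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal AD/MCI cohorts with scheduled visits at 0, 3
    and 6 months, labels cognitive conversion from a 4-point ADAS-cog decline
    rule, and predicts conversion with a hybrid model: a five-layer
    fully connected encoder for static patient features fused with an LSTM over
    visit-level neuropsychological scores, with scaled dot-product attention
    across time steps and teacher-forced training. Includes stratified
    five-fold cross-validated evaluation (ROC/AUC, Youden cutoff,
    Clopper-Pearson intervals), a mid-point withdrawal ablation that removes
    the 3-month visit from trained-model inputs, and a treatment-reassignment
    decision analysis comparing actual against predicted conversion with
    Pearson chi-square and Fisher exact contingency tests, overall and by
    stratum.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
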