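Package: demgrid
Title: Dementia Classification Pipeline for Coronal Slice-Grid MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seeded analysis pipeline for three-class dementia
    classification (cognitively normal, mild cognitive impairment, Alzheimer's
    disease) from T1-weighted structural MRI. Provides a synthetic phantom-brain
    cohort generator with class-graded hippocampal atrophy and ventricular
    enlargement; a five-stage preprocessing pipeline (quality control, brain
    extraction, affine correlation-ratio registration, white-matter-referenced
    intensity normalisation, and 10-slice coronal 512x512 grid construction);
    patient-level stratified train/validation/test splitting with machine-checked
    leakage prevention; class-imbalance mitigation (inverse-frequency class
    weights, Borderline-SMOTE, random undersampling, focal and margin losses);
    desk-scale capsule-network and convolutional baselines with
    routing-by-agreement; and a multi-metric evaluation framework for imbalanced
    multiclass problems (balanced accuracy, ordinal MSE, ROC/PR AUCs, MCC, bias
    index).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    pROC,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
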