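Package: petivim
Title: PET-IVIM Quantitative Analysis for Lymph-Node Metastasis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxelwise intravoxel incoherent motion (IVIM) bi-exponential
    fitting of multi-b-value diffusion MRI, PET metabolic-volume metrics
    (SUVmax, SUVmean, MTV by fractional-SUVmax threshold, TLG), binary
    lymph-node diagnostic evaluation, and a combined logistic/ROC model for
    predicting pelvic lymph-node metastasis. Includes a synthetic-data module
    that generates IVIM/PET phantoms and patient cohorts so the whole
    pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
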