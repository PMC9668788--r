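Package: psmapet
Title: Whole-Body PET/CT Lesion Assessment and Prognostic Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated assessment of whole-body PET/CT lesion segmentations
    downstream of any segmenter. Provides a voxel-grid data model with NIfTI
    input/output, body-weight standardised uptake value (SUV) conversion with
    radioactive decay correction, grid resampling, 3D connected-component
    labelling, a global SUV-threshold baseline segmenter with physiologic-uptake
    exclusion, three-level evaluation of predicted lesion masks (patient-level
    scan classification, lesion-level detection under a volumetric-overlap
    rule, voxel-level segmentation metrics), whole-body tumour-burden
    biomarkers (total lesional volume and uptake), Kaplan-Meier survival
    stratification with log-rank testing, and a synthetic whole-body phantom
    cohort generator with controlled prediction-error modes for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
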