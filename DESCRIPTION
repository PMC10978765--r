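Package: deshkit
Title: Automated Volumetric Assessment of Disproportionately Enlarged
    Subarachnoid-Space Hydrocephalus from 3D MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage automatic assessment of disproportionately enlarged
    subarachnoid-space hydrocephalus (DESH), the imaging hallmark of Hakim
    disease (idiopathic normal-pressure hydrocephalus), from 3D brain MRI.
    Provides a synthetic cranial phantom generator with known cerebrospinal
    fluid compartment geometry, NIfTI volume and label-map input/output, a
    3D U-Net for volumetric semantic segmentation of CSF spaces trained with
    a smoothed Dice loss, an anatomical landmark rule that partitions the
    subarachnoid space into its high-convexity part and the Sylvian fissure
    plus basal cistern, the DESH, Venthi and Sylhi volumetric ratio indices,
    a multimodal convolutional classifier for DESH, ventricular dilatation,
    tightened high-convexity sulci and Sylvian fissure dilatation, and
    ROC analysis with Youden-optimal threshold calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
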