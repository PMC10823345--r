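Package: rlkunet
Title: Large-Kernel 3D U-Net Segmentation of Brain Metastases with
    Volumetric Treatment-Response Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and segmentation of brain metastases on
    contrast-enhanced black-blood T1-weighted MRI with a re-parameterized
    large-kernel 3D U-Net ('RLK-Unet' style architecture: depthwise
    13x13x13 encoder kernels trained as parallel multi-branch blocks and
    algebraically fused to a single kernel for inference, multiscale
    foreground-highlighting decoder supervision), false-positive
    suppression by surface and choroid-plexus masks, lesion-level
    detection and segmentation metrics (sensitivity, precision, false
    positives per scan, Dice, Pearson and Bland-Altman volumetric
    agreement), volumetric modified RANO-BM treatment-response
    classification (complete response / partial response-stable disease /
    progressive disease with the 72.8 percent volume-increase rule), and
    inter-rater agreement statistics (ICC(2,1), percent agreement).  A
    synthetic 3D phantom generator with known ground truth (necrosis
    excluded), vessel and choroid-plexus distractors makes the full
    pipeline reproducible and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    yaml,
    ggplot2,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
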