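Package: ctsegbench
Title: Benchmarking 2D and 3D U-Net Brain Tissue Segmentation in Anisotropic CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparing slice-wise single-task 2D U-Nets
    against patch-based multitask 3D U-Nets for gray matter, white matter and
    cerebrospinal-fluid classification in anisotropic head CT. Provides a
    seeded digital head-phantom generator emitting paired pseudo-CT and
    tissue-label volumes in NIfTI format, Hounsfield-unit windowing and label
    encoding, deterministic sliding-window patch extraction and stitching, a
    self-contained CPU U-Net training and inference engine, argmax and
    global-threshold binarization rules, and segmentation evaluation by
    continuous Dice, average and modified Hausdorff distance, volumetric
    error and cohort-level Pearson correlation of tissue volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
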