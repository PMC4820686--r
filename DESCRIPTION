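Package: kidneyseg
Title: Coarse-to-Fine Kidney Segmentation in CT Slice Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments kidneys from abdominal CT slice sequences with a
    two-stage coarse-to-fine pipeline. The rough stage clusters each
    cropped slice with spatially constrained kernel fuzzy c-means (SKFCM)
    and propagates the crop rectangle slice-to-slice via the extended
    minimum bounding rectangle; the refinement stage runs a GrowCut
    cellular automaton whose foreground/background seed labels are
    generated automatically from the contour of an adjacent,
    already-segmented slice. Includes segmentation evaluation metrics
    (accuracy, Jaccard overlap, sensitivity, specificity), a deterministic
    synthetic phantom generator with ground truth for testing without
    patient data, and readers/writers for NIfTI volumes and PNG/TIFF
    slice stacks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
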