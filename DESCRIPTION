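Package: seegquake
Title: SEEG Electrode Localization and Seizure-Onset-Zone Indices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presurgical stereoelectroencephalography (SEEG) evaluation tools:
    automatic localization of depth-electrode contacts from a skull-stripped,
    co-registered post-implant CT volume (thresholding, 3D Hough-transform line
    detection, Gaussian-mixture clustering, and center-of-mass contact
    segmentation with fixed-pitch stepping), and two per-channel
    seizure-onset-zone indices computed from SEEG recordings: an ictal
    Epileptogenicity Index based on high-gamma onset ranking and an interictal
    High-Frequency Events Index based on 80-250 Hz envelope event counting.
    Includes synthetic CT-volume and SEEG-recording generators with ground
    truth, geometric quality-control metrics, and ROC/AUC evaluation against
    clinician seizure-onset-zone labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    mclust,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
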