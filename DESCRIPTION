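Package: ecgincept
Title: ECG Beat Classification with 1-D Inception Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single-lead ECG heartbeats into five rhythm classes
    (normal sinus rhythm, left and right bundle branch block, atrial and
    ventricular premature contractions) with small 1-D inception
    convolutional networks. Provides R-peak-anchored beat segmentation with
    anti-aliased length normalization, declarative network specifications
    covering one- and two-module inception designs plus a convolution-front
    variant, a basic [1,3,5] and an expanded [10,50,100] kernel set, seeded
    Adam training, confusion-matrix metrics (accuracy, sensitivity,
    specificity, positive predictive value, per-predicted-class
    misclassification error), a patient-specific normal/abnormal evaluation
    protocol, readers for WFDB-style annotated records and a plain-text
    fixture dialect, and a seeded synthetic five-class ECG generator so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
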