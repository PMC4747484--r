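Package: calscore
Title: Calcium Scoring for Ultrasound and Micro-CT Phantom Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies calcium in B-mode ultrasound and micro-CT image
    stacks of tissue-mimicking agar phantoms. Implements a gray-scale
    ultrasound calcium score (sum over slices of thresholded calcium area
    times maximum pixel value, averaged over short- and long-axis sweeps),
    an Agatston-style micro-CT calcium score (Hounsfield-unit calibration
    from water/air references, 700 HU selection threshold, density
    weighting factors), and a calibrated integrated-backscatter (cIB)
    score from per-slice backscatter readings. Ships a synthetic
    nine-speck hydroxyapatite phantom simulator with ground-truth masks,
    plus the validation statistics (Pearson correlation, ROC curves with
    Youden-optimal cutoffs, intraclass correlation coefficients) used to
    compare scores against known calcium masses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
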