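Package: iridoquant
Title: Calibrated Transparency and Iridophore Area Quantification with
    Exact Nonparametric Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying tissue transparency from paired
    transmitted-light micrographs with peripheral-area illumination
    calibration, measuring iridophore coverage by reflectance
    thresholding, and analysing the resulting per-subject measurements
    with exact Wilcoxon rank-sum and signed-rank tests, Steel-Dwass
    all-pairs comparisons and compact letter displays. Includes a
    deterministic synthetic-scene generator with planted ground truth
    for end-to-end validation, and a small command-line pipeline
    (generate, quantify, stats, run-all).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
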