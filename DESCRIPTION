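Package: feulgen
Title: Feulgen Image Densitometry for Absolute Nuclear DNA Content
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-nucleus DNA content (pg) from transmitted-light
    images of Feulgen-stained spread preparations. Converts transmittance to
    optical density, segments nuclei, integrates optical density per nucleus
    (IOD), calibrates IOD to picograms against an internal chicken
    red-blood-cell standard (2C = 2.5 pg), and summarises samples with the
    full descriptive-statistics layer used in image cytometry (skewness,
    kurtosis, CV, SE, 95% CI, pooled statistics, Kruskal-Wallis with Dunn
    post tests, DNA-area correlation, fold-C histograms). Includes a
    synthetic-slide generator with per-nucleus ground truth so the whole
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    e1071,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
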