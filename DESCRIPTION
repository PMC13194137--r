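Package: treedraw
Title: Morphometric Analysis of Tree Drawing Projection Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated extraction of calibrated morphometric features
    (crown, trunk and root areas, heights and widths) from scanned
    tree-drawing projection tests, as used in depression screening
    research. Provides image loading with pixel-to-centimetre
    calibration, ink extraction by Otsu thresholding, silhouette
    partitioning into crown/trunk/roots via width-profile change
    points, a statistical comparison battery (two-sample t-tests from
    raw data or summary statistics, Mann-Whitney, chi-square, Spearman
    correlation, Cohen's d, noncentral-t power analysis), a synthetic
    drawing renderer with analytic ground truth for validation, and a
    batch pipeline from a scan directory plus participant roster to
    publication-style report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jpeg,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
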