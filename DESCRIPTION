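Package: scbcsec
Title: Single-Cell Barcode Chip Secretomic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for multiplexed single-cell secretomic data from
    antibody-barcode microchamber chips (SCBC). Estimates per-analyte assay
    background from zero-cell microchambers with Gaussian fits and
    Kolmogorov-Smirnov diagnostics, corrects linear device background
    gradients, calls secretion at the mean plus two standard deviations
    cutoff, normalizes net signals by the on-chip secretion window, and
    summarizes single-cell polyfunctionality through per-stratum
    polyfunctional strength indices (pSI), cross-condition fold changes,
    and PCA/k-means embeddings. Includes a calibrated synthetic chip
    generator emulating microchamber occupancy, stripe backgrounds, and
    condition-dependent lognormal secretion signals, so every pipeline
    stage is testable without raw chip data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
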