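Package: retvas
Title: Retinal Vessel Density and Arteriovenous Ratio from Smartphone Fundus Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of retinal vasculature in smartphone
    ophthalmoscope fundus photographs. Implements the full processing chain:
    square cropping with physical field-of-view calibration, conversion to a
    565x565 analysis frame, weighted grayscale, contrast-limited adaptive
    histogram equalization (CLAHE), intensity stretching with gamma
    correction, border mean filtering, patch-based U-Net vessel segmentation
    trained on DRIVE-layout or synthetic data, vessel density computation,
    annulus-constrained arteriole-to-venule (A/V) caliber ratio measurement,
    and Bland-Altman test-retest repeatability statistics. Includes a
    synthetic fundus generator with exact vascular ground truth (masks,
    centerlines, per-branch widths, artery/vein labels) for end-to-end
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
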