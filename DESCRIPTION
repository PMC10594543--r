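Package: capiwide
Title: Wide-Field Video Capillaroscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of wide-field skin video capillaroscopy:
    template-matching video stabilization, per-pixel minimum-green temporal
    compositing that reveals capillaries from intermittent red-blood-cell
    passage, flat-field illumination correction, contrast enhancement,
    convolutional (U-Net) capillary segmentation with tiled sliding-window
    inference, connected-component quantification of capillary number and
    area, pixel- and region-level agreement metrics, through-origin
    calibration regression and Bland-Altman analysis. Includes a seeded
    synthetic capillaroscopy-video simulator with full ground truth so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
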