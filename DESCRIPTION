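Package: llpstools
Title: Quantitative Imaging of Biomolecular Condensates and Nucleoprotein
    Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative image analysis for in vitro phase-separation and
    single-molecule experiments. Implements a brightfield droplet-edge
    statistic (Farid derivative filter, sigma-thresholded edge fractional
    area, reference normalization and state diagrams), fluorescence
    condensate segmentation with per-condensate partition coefficients and
    multi-channel line profiles, desk-scale single-molecule localization
    (spot detection, pixel-integrated Gaussian fitting, super-resolution
    rendering), filament tracing from localization data (skeleton contour
    lengths, circular/linear classification, clustering, inter-puncta
    spacing, colocalization), and AFM height-map leveling with median
    projection. A synthetic-scene generator provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
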