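Package: cortexmap
Title: Grey Level Index Profiles, Cortical Border Detection, and CNN
    Filter-Activation Analysis on Synthetic Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative cytoarchitectonic analysis on synthetic
    cell-body-stained cortical images with known laminar and areal ground
    truth.  Generates two-area cortical ribbon phantoms with controlled
    cytoarchitecture; computes grey level index (GLI) images as per-field
    volume fractions of cell bodies; constructs cortical traverses along a
    Laplace field between the layer I/II boundary and the grey/white
    matter boundary and samples GLI profiles along them; summarises mean
    profiles by a 10-component shape feature vector; detects area borders
    with a sliding-window Mahalanobis distance confirmed across window
    sizes by Hotelling T2 tests; trains a desk-scale dual-branch
    contracting/expanding convolutional segmentation network and analyses
    its filter activations with pairwise mutual information to identify
    characteristic, cytoarchitectonically interpretable features at the
    cellular, laminar and areal level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
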