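Package: microgliamorph
Title: Segmentation, Morphometry and Phenotype Classification of Microglia
    in Brightfield Histology
Version: 0.1.0
Authors@R:
    person("Microglia", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for quantifying microglial morphological
    phenotypes in immunostained brain tissue. Converts brightfield images
    (dark cells on a light background) into uniquely labeled single-cell
    extracts via a hybrid soma/process segmentation (CLAHE, top-hat soma
    enhancement, Otsu thresholding, local adaptive segmentation, Hessian
    ridge filtering, endpoint bridging and marker-seeded parallel flood
    fill); computes 18 per-cell morphometric parameters including convex
    hull shape descriptors and Sholl analysis; trains a VGG-style
    convolutional neural network to assign each cell to one of four
    phenotypes (amoeboid, activated, rod-like, ramified); and quantifies
    the conformity between network-based and nearest-centroid
    parameter-based classification, including an exact symmetry test for
    paired contingency tables and exhaustive parameter-subset sweeps. A
    ground-truthed synthetic cell and tissue-tile generator makes every
    stage testable without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
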