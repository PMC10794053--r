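Package: ShootCount
Title: Density-Map Counting of Conifer Shoots with an Unbalanced
    Optimal-Transport Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for counting new shoots in tree-crown imagery by density
    map regression. Converts point annotations into ground-truth density maps
    with a geometry-adaptive Gaussian kernel, trains a small convolutional
    density regressor under a composite loss whose core is an unbalanced
    entropic optimal-transport term with a perspective-guided exponential
    transport cost, and evaluates both detection (precision, recall, average
    precision at an IoU threshold) and counting (MAE, MSE). Includes a
    synthetic crown/shoot scene generator with a height-dependent point
    density emulating UAV perspective, Pascal-VOC and point-annotation I/O,
    and a command-line workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    xml2,
    jsonlite,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
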