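Package: ctcscope
Title: Rule-Based and CNN Recognition of Circulating Tumor Cells in imFISH Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies circulating tumor cells (CTCs) in multi-channel
    immunofluorescence-FISH (imFISH) microscopy fields. Segments DAPI-stained
    nuclei by Otsu thresholding and morphological cleaning (with a
    marker-controlled watershed baseline), gates leukocytes by the CD45
    red-proportion rule, counts CEP8/CEP17 centromere probe signal points with
    a distance-based spot-merge rule, and applies the four-condition manual
    interpretation standard to call each nucleus CTC-positive, CTC-negative or
    excluded. Also provides an AlexNet-style convolutional neural network
    alternative (five convolution plus three fully connected layers) with
    grid-searched hyper-parameters under stratified five-fold cross-validation,
    a seeded synthetic imFISH field simulator with ground truth, and
    confusion-matrix evaluation metrics (sensitivity, specificity, precision,
    F1, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    grDevices,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
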