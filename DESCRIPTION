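Package: enteroquant
Title: Quantification and Spatial Analysis of Enteric Neurons in
    Wholemount Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying enteric neurons in two-dimensional
    wholemount images of the gastrointestinal tract. Reads and writes
    calibrated TIFF images, instance label maps and ImageJ ROI archives;
    normalizes images to species-specific pixel sizes; segments neuron
    somata with a classical multi-scale blob and watershed baseline or
    imports external segmentations; delineates ganglia by morphological
    expansion or probability-map thresholding; calls neurochemical marker
    positivity; performs proximal-neighbor spatial analysis including
    local-thickness based threshold estimation; and scores segmentations
    with instance-matching F1 over IoU thresholds, percentage cell count
    error, mask IoU, Adapted Rand error and variation of information.
    A calibrated synthetic ganglia-scene generator provides ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    clue,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    sp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
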