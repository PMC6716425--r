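Package: pdstriatum
Title: Multi-Modality Striatal Image Analysis for Parkinson's Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dopamine-transporter PET / T1-MR
    analysis of the striatum: a deeply supervised residual 3D encoder-decoder
    for striatal segmentation trained with a composite Dice and cross-entropy
    loss, rigid and affine multimodal registration with label propagation,
    striatal-to-occipital ratio (SOR) feature extraction with k-means
    anatomical subdivision, and SVM classification with leave-n-out
    cross-validation and random-forest feature importance. Includes a
    synthetic 3D brain phantom generator so the whole framework can be
    exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
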