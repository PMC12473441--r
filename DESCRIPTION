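Package: sitsense
Title: Pressure-Mat Sitting-Posture Classification and Sitting-Quality Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for smart-sensing-chair research built around dual 32x32
    seat and backrest pressure mats: a synthetic dual-mat frame generator for
    19 sitting postures, preprocessing (labeling, fixed-range min-max
    normalization, empty-frame removal), an image-style augmentation engine
    (Gaussian noise, shift, rotation, random erasing, elastic deformation),
    five posture classifiers behind one training interface (decision tree,
    random forest, RBF support-vector machine, k-nearest neighbours and a
    shallow two-block convolutional network implemented in compiled code),
    confusion-matrix evaluation, a sensor-resolution degradation study via
    bilinear downsampling, and a Borg CR-10 based sitting-quality score with
    duration-dependent decay, episode segmentation and session analytics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    Rcpp,
    rpart,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    class,
    e1071,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
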