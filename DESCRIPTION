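Package: rectvar
Title: Interfraction Positional Variation of Rectal Tumor Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies day-to-day (interfraction) positional and shape
    variation of the primary gross tumor volume (GTVp) in rectal cancer
    radiotherapy from repeat delineations. Implements two complementary
    measures against a baseline scan: center-of-mass (COM) displacement and
    point-based surface displacement using the bidirectional local distance
    (BLD), with signed right-left / anterior-posterior / cranial-caudal
    decomposition. Summarises per-patient displacement distributions
    (median, IQR, 95th percentile), decomposes population uncertainty into
    systematic (Sigma), random (sigma) and group-mean (GM) errors following
    the Van Herk methodology, and maps per-patient surface statistics onto a
    common reference rectum with directional and height segmentation. A
    seeded synthetic-cohort generator with known ground truth supports
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    optparse
Config/testthat/edition: 3
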