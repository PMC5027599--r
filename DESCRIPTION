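Package: smlmet
Title: Automatic Emitter Identification for Single-Molecule Localization
    Microscopy by Minimum-Error Histogram Thresholding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic analysis of single-molecule localization
    microscopy (SMLM) movies. Every locally brightest spot in every frame is
    fitted with a fixed-width 2D Gaussian point spread function, and the
    bimodal histogram of fitted photoelectron counts is split into false and
    true emitters by unsupervised Bayesian minimum-error thresholding with
    pluggable class-density models (Gaussian-Gaussian and Weibull-Lognormal).
    Includes per-emitter reliability estimation and reliability maps,
    super-resolution rendering, tolerance-radius localization evaluation
    (Jaccard, precision, recall, RMSD) with an optimal one-to-one matcher,
    and a ground-truthed synthetic SMLM movie simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    png,
    withr
Config/testthat/edition: 3
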