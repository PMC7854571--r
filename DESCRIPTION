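Package: cryocascade
Title: Progressive Denoising of Single-Particle Cryo-EM Images with a
    Cascade of Convolutional Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reducing noise in single-particle cryo-electron
    microscopy projection images with a cascade of three convolutional
    denoising autoencoders.  Each block is pre-trained on simulated
    projection stacks corrupted at increasing signal-to-noise ratios
    (low to mid, mid to high, high to clean) and then fine-tuned
    pseudo-supervisedly on the target stack against neighbourhood-mean
    images, so that noise is removed progressively.  The package also
    provides an SNR-calibrated projection simulator for synthetic
    phantoms, histogram-equalization enhancement, PSNR evaluation, and
    clustering of projection images by orientation with matched-class
    precision, recall and F1 scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
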