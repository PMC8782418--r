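Package: waveganCT
Title: Unpaired Wavelet-Framelet GAN Denoising and Quality Analysis for Low-Dose CT
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates virtual standard-dose abdominal CT images from low-dose
    acquisitions with an unpaired least-squares generative adversarial network
    whose generator is a deep convolutional framelet: an encoder-decoder that
    down- and up-samples through the 2D Haar wavelet transform, passing the
    high-pass subbands to the expansive path. Inference runs patch-by-patch
    with overlap averaging. The package also provides a synthetic abdominal
    phantom simulator for unpaired training corpora, the standard quantitative
    image-quality toolbox (ROI statistics in Hounsfield units, image noise,
    contrast-to-noise and signal-to-noise ratios, radially averaged noise
    power spectrum with AUC and peak frequency), radiation dose-report
    arithmetic (CTDIvol, DLP, effective dose), and single-slice CT DICOM and
    plain-text raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
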