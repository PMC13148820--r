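Package: cfspopcode
Title: Population Orientation Coding Under Continuous Flash Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for two-photon calcium imaging of macaque early
    visual cortex under continuous flash suppression (CFS): a synthetic-data
    generator for the 242-condition dichoptic protocol, differential-image
    ROI screening, orientation tuning and ocular-dominance profiling,
    population orientation tuning curves with Gaussian fits and Fisher
    information, a two-step ocular-dominance-dependent gain-control model of
    interocular suppression, linear SVM orientation decoding, and a minimal
    self-attention network for stimulus image reconstruction scored by SSIM.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    e1071,
    jsonlite,
    lhs,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
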