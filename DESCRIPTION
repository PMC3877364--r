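Package: neowmsa
Title: Atlas-Guided Detection and Quantification of White Matter Signal
    Abnormality on Neonatal T2-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated, probabilistic-atlas-guided detection and
    quantification of white matter signal abnormality (WMSA, also known as
    DEHSI) on T2-weighted brain MRI of very preterm infants around
    term-equivalent age.  Provides a procedural brain phantom simulator with
    Rician noise and multiplicative intensity nonuniformity, a probabilistic
    atlas builder with pluggable registration backends, an atlas-prior
    Gaussian-mixture tissue segmentation with discrete-cosine bias-field
    correction, a mean-plus-alpha-SD hyperintensity detector with simulation
    based calibration of alpha, confusion-matrix validation metrics, and
    correlation/regression utilities for relating regional WMSA volumes to
    developmental outcome scores.  Volumes are read and written as NIfTI-1.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
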