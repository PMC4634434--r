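Package: sprfit
Title: Full-Curve Fitting of Angular-Interrogation Surface Plasmon Resonance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing angular-interrogation surface plasmon
    resonance (SPR) biosensor data. Implements a sigmoid-asymmetric model
    that fits a full SPR reflectance curve, including both the total
    internal reflection (critical-angle) step and the plasmon resonance
    dip, so that the critical and resonance angles can be determined
    simultaneously from a single channel. Bulk refractive-index changes
    are removed from sensorgrams by subtracting the calibrated critical
    angle response from the resonance angle (specific adsorption angle).
    A transfer-matrix Fresnel simulator for Kretschmann prism/metal-film
    stacks generates synthetic curves and detector image triplets for
    validation, and an image pipeline turns dark/TE/TM detector frames
    into SPR curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
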