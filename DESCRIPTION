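Package: quollmove
Title: Movement Ecology of Northern Quolls in a Mining Landscape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a GPS and
    accelerometer analysis pipeline for northern quolls (Dasyurus
    hallucatus) tracked on an active Pilbara mine site: screening of GPS
    fixes (HDOP, speed, capture-window exclusions, burst construction),
    vectorial dynamic body acceleration (VeDBA) from tri-axial
    accelerometry, kernel-density movement ranges at the 95% isopleth with
    ad-hoc bandwidth selection, observed-versus-available broad-scale
    habitat models, integrated step-selection functions with relative
    selection strength, and piecewise path models linking habitat,
    temperature, step length and energy expenditure. A synthetic-data
    module generates landscapes, habitat-selective trajectories, degraded
    GPS fixes and accelerometer streams with known ground truth so that
    every stage can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    jsonlite,
    lme4,
    glmmTMB,
    fitdistrplus,
    KernSmooth
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
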