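Package: lqfrac
Title: Linear-Quadratic Survival Models for Protracted and Subfractionated
    Radiotherapy Delivery
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Predicts clonogenic and metabolic cell survival after
    fractionated radiotherapy using the linear-quadratic (LQ) model
    extended with a Lea-Catcheside dose-protraction factor G. Implements
    three published formulations of G (an exposure-pair sum accounting for
    repair during and between beam-on segments, a continuous-protraction
    factor, and an incomplete-repair factor for instantaneous
    subfractions), fits the LQ coefficients alpha and beta from
    dose-response survival curves and the sublethal-damage repair
    half-time from split-dose recovery series, generates seeded synthetic
    survival measurements with the replicate structure of MTT-type
    assays, and provides a study pipeline that evaluates treatment
    schedule grids and compares model predictions against measured
    survival of the F10B16 melanoma and 4T1 breast adenocarcinoma cell
    lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
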