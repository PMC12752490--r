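Package: hifresp
Title: Breath-by-Breath Respirometry and the Heat Increment of Feeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the heat increment of feeding (HIF, also
    called specific dynamic action) in air-breathing divers from
    breath-by-breath respirometry. Converts respiratory flow and expired
    gas-fraction signals into per-breath and per-trial oxygen consumption and
    carbon dioxide production at STPD (flow calibration against a known-volume
    syringe, gas/flow phase alignment, first-order analyzer response-time
    deconvolution, breath segmentation, trapezoidal integration); derives
    bioenergetic statistics (basal and resting metabolic rate, respiratory
    exchange ratio, Kleiber ratio, SDA scope, HIF as a percentage of gross
    energy intake, daily digestive cost); and fits the postprandial oxygen
    consumption time course with a penalized-spline generalized additive mixed
    model (shrinkage smooths, tensor-product interaction, random intercepts for
    animal and day) with posterior-resampled trapezoidal area-under-curve
    estimates. A seeded synthetic-data generator produces flow/gas traces and
    study-design trial tables with known ground truth, so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
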