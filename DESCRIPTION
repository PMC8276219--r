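Package: stresswear
Title: Wearable Stress Detection from Multichannel Physiological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting induced stress from wristband
    recordings of blood-volume pulse, electrodermal activity, skin temperature
    and triaxial acceleration. Simulates labeled cohorts under a lab
    stress-induction protocol, conditions the signals (bandpass filtering,
    rate harmonization, min-max scaling), segments them into fixed-length
    labeled windows, classifies windows with four time-series classifier
    families (dynamic-time-warping nearest neighbour, interval-statistics
    forest, spectral-interval forest, fully convolutional network) under
    per-channel ensembling or channel concatenation, and evaluates
    configurations by Matthews-correlation-driven grid search over window
    size and stride.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
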