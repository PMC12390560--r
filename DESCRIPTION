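Package: tensloop
Title: Digital-Twin Simulation and Bench Evaluation of an EMG-Triggered
    Closed-Loop TENS Platform
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates the signal chain of a wearable electromyography-triggered
    transcutaneous electrical nerve stimulation (TENS) device at the desk:
    synthetic surface EMG with annotated activation bursts, an analog front-end
    model (instrumentation gain, finite CMRR, Sallen-Key band-pass, 12-bit ADC),
    a real-time envelope/threshold event detector, a PI-controlled boost
    converter, and a six-channel biphasic stimulation engine with an
    inter-channel leakage model. Ships the bench evaluation harness used to
    verify the design: detection ROC analysis, closed-loop latency studies,
    converter settling metrics, channel-isolation measurements, battery-life
    projections, and study-design statistics (paired sample size, RMSSD,
    baseline normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
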