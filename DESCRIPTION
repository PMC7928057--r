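Package: skinstretch
Title: Simulation and Analysis of a Two-Actuator Facial Skin-Stretch
    Stimulation Device
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to simulate and evaluate a force-controlled, two-motor
    facial skin-stretch stimulator and the psychophysics built on top of it.
    The package generates 6 Hz / 2 N sinusoidal force pulses with signed
    vertical-horizontal time lags, simulates the 100 Hz current-control loop
    (inverse motor model feedforward plus PID feedback) against a skin-like
    load, verifies delivered lags by threshold onset detection on upsampled
    traces, and analyses temporal-order-judgement (TOJ) responses with
    logistic psychometric fits yielding the point of subjective equality
    (PSE) and just-noticeable difference (JND). Synthetic Bernoulli
    responders and noisy recording sets allow the full pipeline to be
    exercised and validated by parameter recovery without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
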