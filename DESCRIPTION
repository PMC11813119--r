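Package: emasim
Title: Simulation and Optimisation of Sensor-Triggered Ecological
    Momentary Assessment Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and optimising ecological momentary
    assessment (EMA) protocols that combine time-based, sensor-triggered
    event-based, and self-initiated surveys. Detects sedentary, walking,
    and running bouts in minute-epoch wearable streams under parameterised
    rules with directional outlier tolerance and heart-rate wear control;
    simulates when event-based surveys would fire given a periodic device
    sync model, retrospective search spans, refractory intervals, and
    per-window/daily caps; sweeps trigger-rule grids and summarises
    triggers per day as median (IQR) of participant means; computes
    compliance outcomes (response rate, latency, completion time) and
    their daily trends with linear mixed-effects models; and compares
    self-initiated with prompted meal, snack, and drink reporting using
    covariate-adjusted linear models. A synthetic free-living cohort
    generator reproduces the activity, wear, and compliance structure the
    analyses assume, so the whole pipeline runs without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
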