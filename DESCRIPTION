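Package: tapbattery
Title: Touchscreen Cognitive Screening Battery Engine, Simulation and Usability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A headless engine for a five-task touchscreen cognitive screening
    battery (simple visual reaction time, Go/No-Go, visual recognition, Simon,
    and key-swap interference). Generates seeded deterministic trial
    schedules, replays tap-event streams through a session state machine that
    enforces a strict touch-input contract (keys inactive before stimulus
    onset, pre-onset taps ignored, multi-tap suppression), scores reaction
    times, omissions, false alarms and congruency interference effects, and
    simulates virtual respondents with ex-Gaussian reaction times for
    end-to-end testing. Includes a usability-analysis toolkit: System
    Usability Scale (SUS) scoring and banding, skewness/kurtosis normality
    screening, and Spearman rank correlations with confidence intervals, plus
    a synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
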