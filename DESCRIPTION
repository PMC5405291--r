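Package: sleepcoach
Title: Automated Sleep-Restriction Coaching and Trial Analytics for Digital CBT-I
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated coaching engine for app-delivered cognitive
    behavioral therapy for insomnia (CBT-I). Implements consensus sleep
    diary metrics (time in bed, total sleep time, sleep efficiency), a
    negotiable sleep-restriction algorithm with weekly titration and a
    short-sleep safety monitor, a deterministic protocol state machine
    with conversation gating and reminders, per-component treatment
    adherence scoring, a synthetic-sleeper simulator for diary streams
    and two-arm trial datasets, and the accompanying statistical
    pipeline: random-intercept multilevel models with likelihood-ratio
    model comparison, change-score effect sizes, predictive mean
    matching imputation, and clinically-meaningful-change
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    readr,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
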