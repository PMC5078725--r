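Package: simonact
Title: Distributional Analysis of Cognitive Action Control in the Oculomotor Simon Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying cognitive action control with an oculomotor
    Simon task under the activation-suppression framework. Provides a
    generative dual-route (automatic capture vs. controlled selection) race
    simulator with per-participant random intercepts and calibratable
    contaminant rates; velocity-threshold saccade detection for 300 Hz gaze
    traces; the standard trial exclusion filters (amplitude, anticipation,
    late responses, 3-SD outliers); conditional accuracy functions, delta
    plots and delta-slope statistics over reaction-time septiles; and
    random-intercept linear and logistic mixed models of log reaction time
    and accuracy with Wald and F tests. A one-call pipeline runs simulation
    or ingestion through quality control, distributional summaries and
    model fits to a reproducible report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    lme4,
    lmerTest,
    car,
    jsonlite,
    yaml,
    readr,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
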