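Package: dyadsleep
Title: Dyadic Actigraphy Analysis of Human-Dog Co-Sleeping
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Minute-by-minute analysis of paired human and dog actigraphy
    during shared sleep periods. Thresholds per-epoch activity counts into
    binary movement states, builds four-state dyadic transition tables and
    raw transition odds, fits discrete-time logistic Markov transition
    models with lagged partner-movement and time-of-night covariates,
    run-length encodes movement bouts and compares their durations with
    rank-sum tests, links nightly movement to subjective sleep-diary
    ratings through linear mixed-effects models with variance
    decomposition, and generates calibrated synthetic coupled movement
    chains for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
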