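Package: thermalscope
Title: Thermal Performance and Aerobic Scope from Intermittent-Flow Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for turning raw intermittent-flow
    respirometry oxygen traces, cohort survival records and morphometrics into
    population-level thermal-performance summaries for fish. Segments
    flush/measure cycles, fits within-cycle oxygen-depletion slopes with
    quality diagnostics, and converts them to mass-specific oxygen uptake
    (MO2). Estimates resting metabolic rate as a low quantile of validated
    overnight measurements, maximum metabolic rate by a sliding-window search
    over the first post-chase measurement cycle, and absolute/factorial
    aerobic scope with an explicit mortality-as-zero rule. Quantifies recovery
    (percent of scope and of maximum rate, time to half recovery, spline-based
    excess post-exercise oxygen consumption), fits quadratic thermal
    performance curves (optimal temperature, upper pejus temperature,
    functional warming tolerance), temperature coefficients (Q10), allometric
    mass adjustment, and two-parameter log-logistic survival curves (M50 with
    profile-likelihood intervals). Includes a seeded synthetic-data generator
    that emulates the raw inputs so every stage of the pipeline can be
    verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
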