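Package: dialysisCEA
Title: Cost-Utility Analysis of Peritoneal Dialysis First Versus
    Hemodialysis First in End-Stage Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state annual-cycle Markov cohort model comparing a
    peritoneal-dialysis-first strategy with a hemodialysis-first strategy
    for end-stage kidney disease, with discounted lifetime costs,
    life-years and quality-adjusted life-years from government and
    societal perspectives. Includes interval-to-distribution machinery for
    probabilistic sensitivity analysis, Weibull accelerated-failure-time
    mortality with calibration to published life-year targets,
    Kaplan-Meier annual event probabilities, a six-step direct-medical
    cost aggregation, EQ-5D utility scoring with inverse-probability
    weighted regression adjustment, one-way (tornado) sensitivity
    analysis, probabilistic sensitivity analysis and cost-effectiveness
    acceptability curves, plus a synthetic patient-level data generator
    used to exercise every estimation stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    survival,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
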