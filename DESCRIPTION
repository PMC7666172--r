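Package: stresssleep
Title: Stress-Induced Sleep-Like Inactivity and Social Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for accelerometer-based sleep-like inactivity
    scoring in mice, body-temperature coupling with outlier screening,
    social-interaction zone occupancy and susceptible/resilient
    classification, nose-proximity sniffing-bout detection from pose tracks,
    size-filtered fluorescent cell counting, and the accompanying statistics
    layer (Pearson/OLS with confidence and prediction bands, ANCOVA,
    Fisher exact, Kolmogorov-Smirnov, one-way ANOVA with Tukey, mixed-design
    repeated-measures ANOVA with Sidak). Includes a seeded synthetic-cohort
    generator that emulates all input modalities with recorded ground truth
    for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    emmeans,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
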