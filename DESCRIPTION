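Package: pdtask
Title: Simulation and Analysis of Probabilistic-Delivery Operant Gambling Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the probabilistic-delivery task (PDT), a two-choice
    operant protocol in which animals choose between a small certain reward
    and a large reward delivered with a session-specific probability that is
    rarefied across sessions. The package provides species presets (rat,
    marmoset) for the task protocol, a trial-level simulator of synthetic
    cohorts with free-operant Poisson responding and Bernoulli reward
    delivery, per-session behavioral metrics (large-reward preference,
    persistence, restlessness, throughput, experienced odds), and the
    slope-based gambler/non-gambler phenotyping procedure: an inclusion
    filter, a per-subject least-squares slope of preference against
    log(odds + 1), and a within-species median split with an explicit
    median-subject tie rule. Group-level summary tables and an end-to-end,
    fully reproducible pipeline driver are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    yaml,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
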