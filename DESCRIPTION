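Package: chunksim
Title: Simulation and Analysis of Chunked Trial-Sequence Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generative modelling of how long sequences of standalone trials
    are executed as a series of smaller task units ("chunks"), each opened by
    the instantiation of a higher-level control program that elevates the
    reaction time of its first trial. Provides chunk-size distributions and a
    renewal-process recursion for per-position chunk-start probabilities
    (with an exhaustive enumeration oracle), synthetic generators for
    rule-switching, Stroop, instructed-counting and easy/difficult sequence
    experiments, the standard preprocessing chain (warmup removal, error
    exclusion, per-participant 5-SD trimming), and repeated-measures
    statistics (position profiles, linear contrasts, one-way RM-ANOVA,
    switch/Stroop cost trajectories, Holm-corrected paired comparisons).
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
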