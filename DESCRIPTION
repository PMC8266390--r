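Package: photopit
Title: Fiber Photometry and Pavlovian-to-Instrumental Transfer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested, reproducible pipeline for analysing two-channel
    (isosbestic-corrected) fiber photometry recordings together with operant
    behavioral event logs from appetitive Pavlovian conditioning and
    outcome-selective Pavlovian-to-instrumental transfer (PIT) experiments.
    Provides a seeded synthetic-data generator emulating the session designs
    (random-time reward schedules, pseudorandom stimulus orders, interleaved
    415/470 nm acquisition, photobleaching and shared motion artifact),
    isosbestic regression and delta-F/F Z-scoring with quality control,
    peri-event peak and area-under-curve quantification, elevation-ratio
    behavioral scoring, and repeated-measures/mixed ANOVA with
    Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
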