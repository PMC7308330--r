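Package: drumscore
Title: Drum Performance Scoring and Training-Related Plasticity Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective assessment of multi-limb drum performances recorded as
    MIDI event streams, and the statistical pipeline used to relate training
    gains to neuroimaging-derived brain measures. Reads Standard MIDI Files or
    CSV event lists, maps percussion notes to limbs, matches events against a
    metronomic beat grid under a half-beat tolerance, and computes the
    percentage of completed bars, flam (simultaneity) errors, and the
    hi-hat/ride/snare (HRS) coordination error. Provides total-cerebellar-volume
    residualization of lobular volumes, exact Mann-Whitney tests on pre/post
    delta scores, ANCOVA with covariates, rank correlations, and a report
    generator mirroring a two-group pre/post measures table. Includes synthetic
    generators for drummer event streams with controlled jitter, lags, misses
    and extra hits, and for two-group pre/post cohort tables with configurable
    group-by-time effects, so the full analysis is exercisable without any
    external data.
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
    rlang,
    withr,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
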