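Package: ecoclim
Title: Mechanistic Ecoclimatic Suitability Modelling for Maize
Version: 0.1.0
Authors@R:
    person("Eco", "Clim", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A CLIMEX-style mechanistic species distribution model for maize
    (Zea mays L.) on gridded monthly climatology. Computes weekly trapezoidal
    temperature and soil-moisture growth indices over a simple bucket
    hydrology, accumulates cold, heat, dry and wet stress indices, and
    combines them into the annual Ecoclimatic Index (EI). Includes a
    synthetic global climatology generator with GCM-like scenario
    perturbations, equal-area regional change accounting, occurrence-overlay
    validation, one-at-a-time parameter sensitivity analysis, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
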