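Package: trenchshield
Title: Agent-Based Mother-Machine Simulation and Analysis of Collective
    Hydrogen Peroxide Shielding in Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates Escherichia coli cells growing in mother-machine
    trenches under hydrogen peroxide stress, where scavenging by each cell
    attenuates the local concentration experienced by cells deeper in the
    trench. Provides the downstream single-cell analysis pipeline: track
    table input/output and validation, per-cell morphology and growth
    metrics, a 126-feature matrix over mother and barrier cells, random
    forest prediction of stress-response magnitude with grouped feature
    importances, reporter-based calibration of local peroxide
    concentration, per-barrier-cell attenuation inference, time-series
    cross-correlation lag estimation, lineage memory statistics, cell-fate
    classification, and DNA mismatch rate analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
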