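Package: weedclim
Title: Heat-Moisture Coupling and Altitudinal Trend Analysis for Parasitic
    Weed Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links species occurrence records of parasitic weeds (Striga,
    Orobanche, Phelipanche) to monthly gridded land-surface temperature and
    root-zone soil-moisture percentile fields. Provides occurrence cleaning
    and deduplication, lagged point extraction from monthly grids, detection
    of heat-moisture coupling events (hot and wet conditions in the same
    month within a three-month lag window), per-species coupling association
    percentages, tie-corrected Mann-Kendall trend tests, logistic trend
    models for high-elevation occurrence and coupling frequency with
    separation flagging and odds/probability summaries, one-way ANOVA with
    Tukey HSD compact-letter displays, standardized three-variable PCA,
    host-crop presence cross-referencing across two harvested-area epochs,
    and a synthetic scenario generator with planted environmental structure
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
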