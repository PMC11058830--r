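Package: hydroscale
Title: Multi-Timescale Decomposition and Coupling Analysis of Lake, Climate and Vegetation Monthlies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multi-timescale analysis of monthly hydro-climatic and
    vegetation time series: ensemble empirical mode decomposition (EEMD) with
    mean-period estimation and grouping of intrinsic mode functions into noise,
    annual and interannual components; Theil-Sen / Mann-Kendall trend statistics
    and coefficient-of-variation variability classes, scalar and per-pixel;
    penalized (PELT) and binary-segmentation change-point detection with
    per-segment linear rates; and partial-correlation coupling analysis with a
    joint time-lag / time-accumulation grid search. A synthetic-data module
    generates coupled monthly series and raster stacks with known periods,
    trends, break points, lags and accumulation windows for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
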