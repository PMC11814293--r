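Package: sibesim
Title: Simulation and Processing Chain for Grid-Plus-Random Intertidal
    Benthic Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and processing large-scale
    intertidal macrozoobenthos surveys of the kind run on Wadden Sea
    mudflats: construction and yearly maintenance of a 500-m systematic
    grid with additional random stations on gridlines, Monte-Carlo
    evaluation of competing sampling designs (minimum detectable
    difference, prediction error, autocorrelation-parameter bias),
    laboratory counting and subsampling rules with per-square-metre
    standardization, reduction of 126-class laser-diffraction grain-size
    spectra to median grain size and mud content, species-specific LOESS
    biomass-length models with interquartile-range outlier fences and
    hierarchical scale selection for imputing missing ash-free dry mass,
    correlogram estimation with exponential variogram fitting and
    ordinary kriging interpolation, and reading, validation, zero-filling
    and summarisation of the published three-file data model
    (samples.csv, species.csv, biota.csv). A synthetic mudflat-world
    generator with known ground truth drives parameter-recovery and
    power experiments without access to the real archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
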