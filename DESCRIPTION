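Package: marindown
Title: Statistical Downscaling of Marine Climate Projections by Detrended Quantile Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bias correction and statistical downscaling of coarse-resolution
    ocean climate-model fields (temperature, salinity, pH, oxygen, chlorophyll)
    against a high-resolution historical reference using detrended quantile
    mapping (DQM), with equal-weight ensemble statistics, skill evaluation
    against gridded climatologies and point observations (Liu-mean efficiency
    score), and a three-source uncertainty and emergence analysis
    (scenario range, model range, internal variability). Includes seeded
    synthetic-data generators with known truth so the whole pipeline is
    testable end to end, and CF-style NetCDF input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    geosphere,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
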