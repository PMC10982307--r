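Package: eurosoy
Title: Simulation and Scenario Analysis of European Soybean Production Potential
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates soybean phenology, growth and water-limited yield on
    gridded sites from daily weather, using growing-degree-day thermal time,
    an adaptive planting rule, expolinear canopy expansion with radiation-use
    efficiency, and a bucket soil-water balance. Sites are summarised and
    grouped into agroclimatic clusters by spatially constrained Ward
    clustering, and cluster areas and yields feed six land-use scenarios that
    account production, displaced crops, cropland area, fertiliser nitrogen,
    greenhouse-gas emissions and the carbon opportunity cost of spared land.
    Includes seeded synthetic generators for weather, soils, site grids and
    national yield series, plus yield-trend regression, yield-gap and
    trade-conversion utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
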