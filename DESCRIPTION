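Package: termiteCH4
Title: Global Termite Methane Emission Upscaling on Gridded Climate and
    Land-Use Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bottom-up estimation of global termite CH4 emissions on a
    regular latitude-longitude grid. Combines a climate-envelope habitat
    mask (minimum monthly mean temperature above -8 degrees C), land-cover
    specific termite biomass densities with a GPP-driven relationship in
    tropical forests, and Monte-Carlo sampling of observed emission
    factors to produce ensemble global and regional emission totals,
    habitat areas, total biomass, and historical or scenario time series.
    Includes a seeded synthetic driver-data generator (temperature
    climatology, biome mosaic, cropland fraction, GPP, soil CH4 sink,
    emission-factor sample) so the full pipeline runs and is tested
    without external datasets. Gridded fields are read and written as
    CF-style NetCDF or plain CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ncdf4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
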