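Package: elementscape
Title: Trace-Element Basemaps and Likelihood-of-Origin Assignment for Migratory Wildlife
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds continuous spatial prediction surfaces ("elementscapes")
    from multi-element tissue chemistry of known-origin individuals and
    assigns individuals of unknown origin to likelihood-of-origin surfaces.
    Implements geographically weighted principal component analysis of
    element concentration profiles with cross-validated bandwidth selection,
    inverse-distance-weighted interpolation of component scores, indirect
    basemap extension through per-element soil-to-tissue transfer
    regressions, normal-density assignment surfaces with threshold and
    travel-buffer classification rules, and leave-k-out cross-validated
    accuracy and precision evaluation. Includes a synthetic-landscape
    generator emulating spatially autocorrelated soil element fields and
    weakly coupled tissue chemistry, so the whole pipeline is testable at
    desk scale, plus readers and writers for sample tables, ASCII grid
    rasters, and GeoJSON range polygons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    ape,
    geosphere,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
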