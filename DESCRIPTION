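Package: firetrends
Title: Multi-Decadal Forest Fire Activity: Burned Area, Fire Weather and
    Years-Since-Last-Fire Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-decadal forest fire activity on
    regular latitude-longitude grids. Reconstructs per-pixel
    years-since-last-fire surfaces from annual fire histories using a
    geometric-quantile initializer, aggregates monthly burned-area rasters
    to July-June fire years with union (not-recounted) accounting, computes
    gridded fire-weather risk factors (McArthur Forest Fire Danger Index
    with Keetch-Byram drought index and Griffiths drought factor,
    continuous Haines index, dry-lightning days), and fits the linear and
    log-linear trend and burned-area regression models used to relate
    burned area to fire weather. A synthetic-data module generates fire
    histories, daily weather cubes and monthly burned-area products with
    known parameters so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
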