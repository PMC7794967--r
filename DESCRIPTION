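Package: karsthealth
Title: Grid-Based Ecosystem Health Assessment for Karst Mining Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grid-based ecosystem health (ESH) assessment of karst
    mining regions from categorical land-use rasters, terrain and
    socio-economic surfaces. Implements land-use transition matrices and the
    ecological change-direction score (LCDM), a twelve-indicator
    pressure-state-response (PSR) composite index on a 2 km fishnet with
    min-max normalization and AHP-style fixed weights, Jenks natural-breaks
    health classification, an urbanization index (population, per-capita GDP,
    construction-land proportion), global and local bivariate Moran's I with
    Monte-Carlo permutation inference, and mine-buffer zonal analysis. A
    synthetic scene generator (Markov land-use dynamics, smooth terrain,
    kernel-based population and GDP surfaces, clustered mine belts) makes the
    whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
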