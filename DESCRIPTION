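Package: partmig
Title: Individual-Based Simulation of Partial Migration Under a Genetic
    Threshold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit individual-based model of a haploid species
    with discrete generations living on a pole-to-equator gradient of winter
    survival and reproduction. Each individual carries a heritable migration
    threshold; it migrates whenever its expected local winter survival falls
    below that threshold, producing an evolving cline from fully migratory
    to fully residential populations with a zone of partial migration in
    between. The package provides the generation cycle (migration decision,
    density-dependent winter survival, dispersal with reflecting borders,
    density- and location-corrected reproduction with mutation), a catalog
    of initialization and abrupt environmental-change scenarios, replicate
    runners, and summary statistics locating the partial-migration zone and
    the range front, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
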