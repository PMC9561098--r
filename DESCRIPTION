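Package: cushionbench
Title: Bench-Test Classification of Wheelchair Cushion Pressure-Management Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to evaluate and classify wheelchair cushion pressure-management
    performance from dual buttock-model, dual-load pressure-sensor bench trials.
    Implements the two performance parameters (surface pressure redistribution as
    the bony-site fraction of total surface pressure, and internal pressure
    magnitude as the ratio of summed internal pressures to a flat-foam reference),
    confidence-interval pooling across load conditions, equivalence-band
    trichotomous classification, a five-tier overall category matrix, median-based
    outlier flagging with axisymmetric-pair imputation, and a seeded synthetic
    trial simulator that stands in for the physical test rig.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
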