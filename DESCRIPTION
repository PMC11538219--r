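Package: spherostress
Title: Growth-Induced Solid Stress Analytics for Gel-Embedded Macrophage Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for studying the solid stress generated by
    macrophage spheroids growing inside confining agarose hydrogels. Provides a
    2-D plane-strain linear-elastic finite-element model of the gel deformation
    driven by prescribed cavity-expansion boundary conditions, with the
    closed-form Lame annulus solution as a built-in verification oracle;
    Young's modulus extraction from unconfined-compression stress-strain
    curves with automatic linear-region detection; image-based spheroid
    morphometry (area, solidity, eccentricity) and live/dead viability
    counting; relative qPCR quantification (2^-ddCt) with Grubbs outlier
    rejection and the accompanying nonparametric group tests; and a
    synthetic-data generator that produces every pipeline input with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
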