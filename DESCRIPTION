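Package: sharktrace
Title: Maternal Elemental Tags and Gestation Migration Patterns from Shark
    Vertebral Microchemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces time-resolved laser-ablation ICP-MS (LA-ICP-MS) signals
    from elasmobranch vertebrae to calibrated element:Ca spot signatures and
    distance-resolved transect profiles (background subtraction, iterative
    Grubbs despiking, linear sensitivity-drift correction, NIST-612 external
    calibration, 43Ca internal standardization, 3-sigma gas-blank limits of
    detection, robust replicate screening). Provides distance-based statistics
    for maternal-tag hypotheses (one-way PERMANOVA, canonical analysis of
    principal coordinates with leave-one-out cross-validation, proportional
    chance criterion), classifies in utero Sr:Ba / Pb:Ca transect profiles into
    gestation migration patterns, locates the maternal habitat-shift point, and
    back-calculates embryo length at that point with the Fraser-Lee model. A
    seeded synthetic-data generator emulates complete instrument run sequences
    with known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    MASS,
    jsonlite
Config/testthat/edition: 3
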