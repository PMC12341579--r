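Package: woundring
Title: Quantification of Actomyosin Purse-String Wound Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify epithelial wound closure driven by a
    supracellular actomyosin cable ("purse string"). Detects and tracks the
    constricting ring in fluorescence time-lapse movies, extracts
    circumferential kymographs, detects and classifies myosin clusters as
    radial or tangential from their arc speed, fits laser-ablation recoil
    traces to a viscoelastic tension model, relates ratiometric RhoA-FRET
    activity to myosin density around the ring perimeter, and computes
    cohort-level statistics. Ships a ground-truthed synthetic movie
    generator so every stage is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
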