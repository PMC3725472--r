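Package: sfamaze
Title: Place-Cell and Head-Direction-Cell Simulation with Hierarchical
    Slow Feature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a virtual rat foraging in configurable 2-D enclosures,
    renders its panoramic visual stream with a deterministic software
    raycaster, and trains a three-layer Slow Feature Analysis (SFA) network
    with an optional independent-component-analysis (ICA) sparse-coding step
    on the rendered frames. Trained networks are probed over the enclosure to
    produce place-field rate maps and head-direction tuning curves, the
    simulation analogue of hippocampal place-cell and head-direction-cell
    recordings. Includes enclosure presets (box, circle, star maze) and a
    plain-text floor-plan format, a statistical movement model with momentum
    and turn limits plus waypoint-following paths, batch training for long
    image streams, and a four-stage command-line pipeline
    (record, convert, train, sample).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    png,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
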