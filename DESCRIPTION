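Package: geledge
Title: Interfacial Edge Effects in Supported Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the mechanical edge effects a rigid support imposes on a
    soft hydrogel and their consequences for embedded cells. Provides an
    axisymmetric finite-element simulator of rigid-sphere indentation on a
    finite-thickness elastic gel (effective stiffness and von Mises stress
    versus gel height), a seeded synthetic-microscopy generator emulating
    z-dependent cell morphology and migration statistics, z-resolved cell
    morphometry (area and moment-ellipse aspect ratio), drift-corrected
    time-lapse cell tracking, and the accompanying two-sample and rank-based
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    minpack.lm,
    tiff,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
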