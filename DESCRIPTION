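Package: fibersense
Title: Simulated Fluorescence-Microscopy Fiber Counting and Airborne
    Concentration Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end, fully synthetic test bench for automated
    fluorescence-microscopy counting of airborne asbestos fibers collected
    on membrane filters.  Generates seeded ground-truth scenes and defocused
    z-stacks, fuses them into extended-depth-of-field composites by local
    Laplacian-energy focus stacking, detects and measures fiber candidates
    with skeleton-based morphometry against the standard counting criteria
    (length > 5 um, width < 3 um, aspect ratio > 3:1), converts counts to
    airborne concentrations (fibers per liter) from the sampling geometry,
    and provides agreement statistics: relative-difference Bland-Altman
    limits of agreement and Poisson counting-variability simulations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
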