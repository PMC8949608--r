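Package: depsweep
Title: Closed-Loop Characterization of Dielectrophoretic Frequency Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for automatically classifying positive and negative
    dielectrophoresis (DEP) regimes and bracketing the crossover frequency of a
    microbead suspension. Implements the frequency-domain DEP physics
    (complex permittivities, Clausius-Mossotti factor, crossover solving), a
    virtual interdigitated-electrode testbed with overdamped Brownian bead
    dynamics and synthetic microscopy rendering, Hough-gradient circle
    detection, sliding-window least-squares trend classification, and a
    closed-loop feedback controller driving a mock SCPI function generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
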