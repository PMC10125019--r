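Package: ripplemapr
Title: Detection and Propagation Analysis of Hippocampal Sharp-Wave Ripples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hippocampal sharp-wave ripples in multi-probe local field
    potential recordings (Butterworth band-pass, Hilbert envelope, dual
    amplitude thresholds, spectral validation, behavioural exclusion) and
    quantifies their propagation along the medio-lateral hippocampal axis:
    pairwise strength correlation and lag analysis, cross-probe event
    clustering with seed identification, strength-conservation and spatial
    engagement indices, peri-ripple spiking engagement, and ripple modulation
    of sorted units. Ships a multi-probe forward simulator with known ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    signal,
    e1071,
    jsonlite,
    yaml,
    arrow,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
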