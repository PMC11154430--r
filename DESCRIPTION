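Package: gaitdmd
Title: Hankel Dynamic Mode Decomposition of Plantar Pressure Gait Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processes pressure-sensitive walkway recordings into per-step
    plantar force signals, decomposes each step with Hankel (time-delay)
    dynamic mode decomposition into damped-sinusoid modes characterized by
    decay rate, frequency and initial condition, builds per-walker centroid
    baselines over the mode triplets, and identifies walkers by a
    spread-weighted nearest-centroid cost with a Monte-Carlo evaluation
    protocol. Includes a synthetic walkway simulator with known ground-truth
    mode parameters for end-to-end testing without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
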