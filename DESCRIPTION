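Package: polyrisk
Title: Additive Polyrisk Scores for Psychosis Risk Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Build additive polyrisk scoring systems for psychosis from
    relative risks and population prevalences: raw scores as base-10
    logarithms of relative risks, prevalence-weighted centering so the
    population mean is zero, scaling and rounding to a half-integer grid.
    Score individual factor profiles (with principled handling of missing
    factors), convert total scores to equivalent relative risks,
    characterise the score distribution in a hypothetical general
    population by exact convolution and by seeded Monte-Carlo simulation,
    and perform likelihood-ratio pre-/post-test probability updating for
    sequential detection strategies. Ships a default configuration for the
    Psychosis Polyrisk Score (PPS) prototype together with a synthetic
    cohort generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
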