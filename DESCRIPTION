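Package: widenedpipe
Title: The Widened Pipe Model of Xylem Conduit Widening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Widened Pipe Model (WPM) of tip-to-base xylem
    conduit widening: the closed-form universal widening profile that arises
    from a Pareto trade-off between Hagen-Poiseuille hydraulic resistance and
    the cost of rapid conduit widening, together with the full downstream
    analysis pipeline. Provides per-plant one-parameter least-squares fitting
    of the WPM and competing widening models, pooled normalization and
    equal-population binning with chi-square model comparison, per-plant
    resistance, carbon-cost and conductance accounting, Pareto-front
    construction in resistance-widening space, an independent variational
    (Euler-Lagrange and direct-minimization) oracle for the closed form, and
    a synthetic cohort generator emulating field-sampled conduit-diameter
    profiles so the whole pipeline is testable without the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
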