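Package: celldecide
Title: Quantifying Cell Decision-Making Errors from Single-Cell Response
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Treats a cell's reading of its environment as a binary
    hypothesis test and quantifies how often signal transduction noise
    makes the cell decide wrongly. From single-cell response measurements
    (for example nuclear NF-kB levels after TNF stimulation at low and
    high doses) the package fits per-condition Gaussian response models,
    solves for the maximum-likelihood decision threshold, and computes
    false-alarm, miss and overall error probabilities in closed form,
    by Monte-Carlo integration for joint early/late (bivariate) readouts,
    or directly from empirical histograms. Includes fixed-threshold
    analysis of signaling-deficient cells, dose sweeps of the overall
    error, a closed-form radar reference model, and a synthetic
    single-cell data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    jsonlite,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
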