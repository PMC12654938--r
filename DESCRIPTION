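Package: screeneval
Title: Combined-Weight Performance Evaluation for Stroke-Screening Base Hospitals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-criteria performance evaluation of the base hospitals
    that run community stroke-screening programmes. Implements the threshold-band
    indicator scoring scheme used in annual quality-control reviews, subjective
    weighting from expert-assigned indicator scores, objective weighting by the
    entropy weight method (min-max and moderate-attribute normalisation, zero-shift,
    information entropy), combined weighting by multiplicative synthesis with
    normalisation, total weighted scores and hospital rankings under each
    methodology, and inter-methodology agreement metrics (head-tail consistency
    rate and discrimination degree). Includes a seeded synthetic-panel generator
    for testing pipelines without access to programme data, file input/output for
    CSV and XLSX matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
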