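Package: odnaseg
Title: Heteroplasmy Variance Dynamics and Bottleneck Inference for Organelle DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for the segregation of organelle DNA (mtDNA and
    ptDNA) heteroplasmy. Provides closed-form contributions of cell division,
    turnover, gene conversion, subsampling and reamplification to normalised
    cell-to-cell heteroplasmy variance; closed-form mean and variance of
    heteroplasmy under selection; an exact Gillespie simulator of cellular
    oDNA populations with fission-fusion structure, copy-number feedback,
    biased gene conversion and clustered autophagy; sampling distributions
    for partitioning at division and Polya-urn reamplification; developmental
    schedules for the mouse female germline; and maximum-likelihood inference
    of bottleneck mechanisms (with bootstrap intervals and AIC model
    comparison) from single-cell heteroplasmy measurements, together with a
    synthetic-data generator emulating clustered oocyte studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
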