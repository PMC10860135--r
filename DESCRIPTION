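Package: cspal
Title: Active Learning of Committee Potentials from Crystal Structure
    Prediction Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains committee machine-learned potentials from crystal
    structure prediction (CSP) landscapes by query-by-committee active
    learning. Supports delta-learning of energy corrections against a cheap
    baseline potential, atom-centered symmetry function descriptors with
    CUR-based selection, farthest point sampling, landscape reranking with
    high-uncertainty flagging, and threshold Monte Carlo with an energy lid
    and on-the-fly training. Ships a surrogate baseline/target oracle pair
    and a synthetic rigid-molecule landscape generator so the whole workflow
    runs at desk scale without electronic-structure codes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
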