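Package: mcrfupdate
Title: Categorical Map Updating by Markov Chain Random Field Cosimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for updating categorical raster maps (e.g. soil class
    maps) from sparse point samples together with an exhaustive legacy
    map. Implements experimental transiogram estimation with piecewise
    linear transiogram models, cross-field transition probability matrix
    (CTPM) estimation, random-path sequential simulation under the
    simplified Markov chain random field model (MCSS) and its colocated
    cosimulation extension (Co-MCSS), occurrence-probability
    post-processing with optimal prediction maps, accuracy assessment by
    percentage of correctly classified cells, and a synthetic scenario
    generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
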