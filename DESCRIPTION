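Package: msgnet
Title: Mixed-Species Group Association Networks Along Stress Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mixed-species groups (MSGs) of savanna
    mammals along environmental stress gradients: scenario classification
    (minimum convex polygon predator home ranges, NDVI tertiles, core/edge
    zones), logistic regressions of MSG occurrence with odds ratios,
    Dice-index species association networks with weighted node measures,
    fixed-margin (checkerboard-swap) matrix randomisation tests for dyadic
    associations with an optional habitat-stratified null, node-label
    permutation tests of assortative mixing, and a synthetic sighting
    generator with planted structure for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
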