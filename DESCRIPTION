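Package: poroeco
Title: Bioeconomic Modelling of Reindeer Husbandry Under Variable Winter
    Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An age- and sex-structured bioeconomic model of the
    reindeer-lichen system used in Fennoscandian reindeer husbandry.
    The package couples per-class winter energy budgets (cratering-limited
    lichen intake, diet choice between ground lichen, other cratered
    forage and supplementary feed) with condition-dependent fecundity and
    survival, a two-sex harmonic-mean mating system, lichen pasture
    dynamics, and cash-flow accounting.  On top of the simulator it
    provides dynamic harvest optimization to economically optimal steady
    states, single-winter perturbation experiments, and
    certainty-equivalence feedback optimization over stochastic sequences
    of easy, normal and difficult winters, with or without supplementary
    feeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
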