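Package: coresampler
Title: Core Subset Selection for Germplasm Collections
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Fixed-size core subset selection from plant germplasm
    collections. Selects k of n accessions by maximizing distance-based
    diversity (entry-to-nearest-entry), representativeness
    (accession-to-nearest-entry), allelic richness (expected
    heterozygosity), or a normalized weighted combination of measures,
    using stochastic local search over the single-swap neighbourhood:
    random descent, parallel tempering (replica exchange), and a genetic
    algorithm. Includes Modified Rogers and Gower dissimilarities,
    PAM-based GDOpt and iterative-elimination (SimEli) baseline
    selectors, seeded synthetic marker/trait data generators, and an
    experiment harness for Pareto weight sweeps and algorithm
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
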