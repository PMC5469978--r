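Package: popgravity
Title: Population Graphs and Gravity Models for Landscape Genetic Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing functional connectivity among patchily
    distributed populations from codominant microsatellite genotypes.
    Computes population-pairwise genetic distances (proportion of shared
    alleles, Weir-Cockerham theta), builds conditional-independence
    population graphs with edge-exclusion-deviance pruning and conditional
    genetic distance, summarises network topology (community detection,
    core-periphery concentration, centrality), simulates local extinction
    by random node removal, derives at-site and between-site landscape
    covariates from gridded rasters, and fits singly constrained
    mixed-effects gravity models of gene flow with AICc multimodel
    inference. Includes a seeded synthetic-data generator (Balding-Nichols
    genotypes, Gaussian random-field landscapes, planted gravity flows)
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
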