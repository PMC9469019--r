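Package: kinflow
Title: Kinship-Based Contemporary Gene Flow and Migration Networks from
    Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for temporally structured population-genetic analysis of
    codominant microsatellite data: GenAlEx and STRUCTURE file interchange,
    per-population diversity statistics, rarefaction of distinct and private
    allelic richness, Nei's standard genetic distance with principal
    coordinates analysis and Mantel tests of isolation by distance,
    likelihood-based parent-offspring assignment with an explicit genotyping
    error model, contemporary migration-rate estimation from parentage
    counts, directed migration networks with fast-greedy modularity
    clustering, source/sink classification and key-node reports, and a
    forward-time metapopulation simulator with ground-truth pedigree for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
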