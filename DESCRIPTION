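Package: rescuesim
Title: Forward-Time Individual-Based Simulation of Genetic Rescue and
    Managed Connectivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-time, individual-based simulator of a migrant-recipient
    population and a migrant source population of diploid individuals carrying
    1200-SNP genotypes (neutral, migrant-diagnostic and selectively constrained
    locus classes).  Models a habitat crash via a carrying-capacity schedule,
    logistic reproduction with an Allee mate-finding effect, age- and
    mutation-load mortality, and four managed-connectivity regimes (none, one
    migrant per generation, a single burst, or repeated pulses of
    translocated individuals) with two timing variants.  Monitors observed and
    expected heterozygosity, Nei F_IS, Weir-Cockerham F_ST against year-0
    population snapshots, migrant ancestry, effective migrants and parents,
    sex ratio and lifetime reproductive success, and summarizes replicate runs
    with 84% quantile bands.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
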