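Package: invasim
Title: Individual-Based Simulation of Plant Invasions on Model Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genetically explicit, individual-based model of plant
    communities on a gridded oceanic island with a radial temperature
    gradient and a linear precipitation gradient. Vital rates follow the
    Metabolic Theory of Ecology, environmental adaptation is the product
    of Gaussian niche functions for temperature and precipitation, seeds
    disperse with a log-logistic kernel, and reproduction is sexual with
    meiotic recombination of diploid genomes. The package runs full
    factorial in-silico invasion experiments (propagule pressure,
    temperature as a productivity proxy, disturbance), writes TSV census
    logs and island maps, and categorizes species as native, alien or
    invasive for community trait analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
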