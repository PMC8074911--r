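Package: ecosync
Title: Synchrony Groups and Chimeric Elements in Ecological Oscillator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying phase synchronization in consumer-resource
    networks. Each trophic link (a predator, parasitoid or disease attacking a
    host) is treated as an intrinsically cyclic oscillator; links sharing a
    species are coupled, yielding an adjacency-disaggregated Kuramoto model on
    the line graph of the food web. The package derives the coupling network
    from an edge list, integrates the phase dynamics with a deterministic
    fixed-step solver, detects synchrony groups by a chordal-distance
    criterion, classifies persistent groups and chimeric elements across
    random-initialization replicates, and runs coupling-strength sweep
    experiments, including keystone-oscillator downweighting. A transcribed
    coffee pest/natural-enemy network and a synthetic guild-and-bridge web
    generator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    generics,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
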