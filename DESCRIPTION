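Package: prophageContinuum
Title: Prophage Gene-Repertoire Evolution Along the Parasitism-Mutualism
    Continuum
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and analyses of the gene content of prophages as they
    evolve between parasitism and mutualism. Provides an eight-genotype
    selection-degradation ODE model of beneficial, excision and re-infection
    gene classes with equilibrium regime classification; an individual-based
    Wright-Fisher simulator of bit-string prophages with gene deletion,
    transposable-element disruption, induction, selection, re-infection and
    carrying-capacity regulation; and an annotation-based gene-repertoire
    analysis with proportional bootstrap enrichment tests, insertion-sequence
    transposase classification and length-stratified transposase densities.
    Includes a synthetic PHASTER-style annotation generator and published
    count tables as fixtures, so every stage runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
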