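Package: phylodiag
Title: Incongruence Diagnostics and Morphological Phylogenetics for
    Phylogenomic Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnosing gene-tree/species-tree incongruence and for
    analysing discrete morphological characters on a molecular backbone
    phylogeny.  Includes per-orthogroup filtering statistics (occupancy, tree
    length, saturation, compositional heterogeneity, mean patristic distance),
    Patterson's D with block-jackknife z-scores and a five-taxon D-FOIL
    system, Monte-Carlo estimation of the hemiplasy risk factor on
    coalescent-unit species trees, and an Mk-model toolkit for morphology:
    rescaled Gower distances, implied character weighting and k-means
    partitioning, likelihood-based phylogenetic placement with gamma rate
    variation and the Lewis ascertainment correction, marginal ancestral
    states, and AIC-weighted rate-shift tests.  A coalescent simulator
    (species trees, multispecies-coalescent gene trees with introgression
    pulses, sequence and Mk character matrices, occupancy masks) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
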