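Package: osmundnet
Title: Distance-Based Phylogenetic Networks for Morphological Character
    Matrices of Osmundalean Ferns
Version: 0.1.0
Authors@R:
    person("Osmundnet", "Developers", email = "osmundnet@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing categorical (binary/ternary) morphological
    character matrices of fossil and extant royal-fern (Osmundales) axes with
    distance-based phylogenetic networks.  Provides NEXUS matrix input/output,
    derived quantitative character coding (perforations per millimetre of
    stele perimeter, relative cortex thickness) with one-dimensional k-median
    state thresholds, taxon-sparsity and invariant-character filtering, mean
    Hamming distances with pairwise deletion, quartet delta-value
    treelikeness statistics, neighbour-net circular split systems with
    non-negative least-squares split weights, BioNJ and Fitch-parsimony tree
    builders, character-resampling bootstrap supports and frequency-weighted
    consensus networks, a synthetic-matrix simulator with known truth, and a
    command-line pipeline for whole-matrix and subset analyses including the
    placement of newly described taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
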