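Package: orthopipe
Title: Ortholog Clustering, Conserved-Block Identity and Supermatrix
    Phylogenies for Proteome Comparisons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale comparative-genomics pipeline for multi-species
    protein sets: isoform-aware proteome input, all-against-all similarity
    search with Karlin-Altschul E-values, Markov clustering of the reciprocal
    hit graph into ortholog groups, rule-based orthology categorisation
    (universal single/multi copy, lineage-restricted, species-specific,
    patchy), progressive multiple alignment with conserved-block extraction,
    block-restricted percent-identity comparison with closest-relative
    classification and lowess smoothing, and neighbor-joining supermatrix
    phylogenies with column-resampling bootstrap. Includes a ground-truthed
    proteome evolution simulator (stationary Poisson replacement model on a
    species tree with gene duplication) whose closed-form expected identity
    makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
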