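Package: treeseq
Title: Succinct Tree Sequences for Forwards-Time Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recording, storing and analysing the genealogical
    history of individual-based population genetics simulations as succinct
    tree sequences.  A tree sequence encodes the correlated genealogies along
    a recombining chromosome in four columnar tables (nodes, edges, sites and
    mutations); shared branches between adjacent trees are stored once.  The
    package provides the table data model with validation, canonical sorting
    and a plain-text interchange format; a linear-time simplification
    algorithm that reduces a tree sequence to the minimal history of a chosen
    sample set by backwards-in-time propagation of ancestral segments; a
    discrete-generation haploid Wright-Fisher simulator that records nodes
    and edges at each birth and periodically simplifies; retrospective
    placement of neutral mutations on the recorded genealogies; marginal-tree
    traversal, genotype generation, nucleotide diversity, and Newick/VCF
    export; and closed-form coalescent predictions for the size of simplified
    tables, usable as test oracles.
License: MIT + file LICENSE
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
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
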