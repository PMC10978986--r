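Package: coactomics
Title: Genome-Resolved Co-Activity Networks and Community Metabolic
    Cross-Feeding Analysis for Marine Prokaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for genome-resolved analysis of
    bacterioplankton communities: genome quality classification and
    ANI-based species dereplication, meta-omics activity profiling
    (identity filtering, coverage, breadth-based detection,
    metatranscriptomic/metagenomic activity ratios), genomic scaling-law
    enrichment scans, compositionally-aware (CLR) partial-correlation
    network inference with conditional-independence pruning, Markov
    clustering of co-activity graphs, constraint-based community
    metabolic modelling (minimal media, resource overlap, interaction
    potential, cross-feeding scores), and null-model community typing
    with functional Gini and Jaccard statistics. A synthetic-data module
    generates every input at desk scale with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
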