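Package: otunet
Title: Network-Based OTU Clustering of 16S rRNA Amplicons with k-mer
    Prefiltering
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Clusters quality-controlled 16S rRNA amplicon reads into
    operational taxonomic units (OTUs) by a two-pass network method:
    exact-duplicate dereplication with abundance tracking, a hash-coded
    k-mer distance prefilter calibrated by sampling against the
    Needleman-Wunsch dissimilarity, greedy peeling of the most-connected
    (abundance-weighted) nodes of the resulting sequence network, and a
    refinement pass that re-clusters seeds and singletons at the exact
    alignment threshold.  Includes a chunked all-pairs distance scheduler
    with a deterministic merge contract, pair-counting accuracy metrics
    (precision, recall, F-measure) against strain labels, and a seeded
    mock-community read simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
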