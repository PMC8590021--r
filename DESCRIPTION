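Package: shapetf
Title: DNA-Shape-Based Prediction of Transcription Factor Binding Affinity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts transcription factor binding affinity from local DNA
    shape. Scans a genome with a position weight matrix at an exact p-value
    threshold, labels motif occurrences with amplified DNA affinity
    purification sequencing (ampDAP-seq) peak signal, translates sequence
    windows into 13 per-position DNA shape features through a pentamer query
    table, trains a cross-validated random forest regressor on the shape
    features, evaluates it by precision-recall against a motif-only baseline,
    attributes predictions to individual shape features with exact
    interventional Shapley values, and designs novel high- and low-affinity
    motif-containing sequences. Includes a synthetic-data generator (genomes,
    planted motifs, shape-dependent affinities, peak files) so the entire
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    graphics,
    ranger,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
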