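Package: samplemotifs
Title: Sample-Specific Labeled Network Motifs in Directed Network Samples
Version: 0.1.0
Description: Detection of directed subnetworks with fixed, pairwise-different
    vertex labels that are overrepresented across a sample of equally sized
    simple directed networks, such as EEG effective connectivity networks.
    Induced connected k-subnetworks are enumerated exhaustively in every
    sample element; degree-sequence-preserving null ensembles are generated
    by an edge-switching Markov chain whose mixing parameter and ensemble
    size are calibrated from the data (chi-square-style uniformity index
    with Monte-Carlo quantiles, bootstrap convergence of subnetwork
    frequencies); significance is assigned by an exact Poisson-binomial
    tail test with Bonferroni-Holm familywise error control.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
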