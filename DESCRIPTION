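Package: motifClique
Title: Exact Planted (l,d)-Motif Discovery by Recursive Reference-Vertex
    Clique Search
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Exact, sample-driven discovery of planted (l,d) motifs in DNA
    sequence sets under the one-occurrence-per-sequence (OOPS) assumption.
    Enumerates all m-cliques of length-l substrings (one per sequence) whose
    pairwise Hamming distances do not exceed 2d, using a recursive
    reference-vertex search with cumulative candidate-set filtering and
    backtracking. Includes an analytic motif-difficulty probability, a
    base-position recall metric, consensus derivation from cliques, a
    synthetic planted-motif dataset generator, brute-force reference
    solvers for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, Transcription
RoxygenNote: 7.3.3
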