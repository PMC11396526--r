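Package: fullerzz
Title: Zhang-Zhang Polynomials, Ring-Spiral Isomer Generation and Pauling
    Bond Orders for (5,6)-Fullerenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the topological analysis of (5,6)-fullerenes and
    related pentagon/hexagon polycyclic carbon frameworks. Generates
    fullerene isomers exhaustively by the ring-spiral algorithm with
    canonical lexicographic labelling, computes the Zhang-Zhang (Clar
    covering) polynomial of a plane molecular graph by memoized recursive
    decomposition, and derives the classical resonance-theoretic invariants:
    the Kekule count, the Clar count, the Clar number and the number of Clar
    formulas. Also provides Pauling-Kekule and Pauling-Clar pi bond orders
    with linear bond-length prediction models, isomer-stability analyses
    over externally supplied energy tables, molecular graph input from XYZ
    coordinates or adjacency lists, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
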