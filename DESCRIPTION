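Package: MLCSdag
Title: Exact Multiple Longest Common Subsequence Search via a Leveled DAG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact solvers for the multiple longest common subsequence
    (MLCS) problem on DNA, protein or arbitrary-alphabet sequence sets.
    The core engine builds a leveled directed acyclic graph over match
    points level by level, deleting outdated (zero in-degree) nodes as
    soon as they can no longer contribute and accumulating partial
    common subsequences in the graph, so that the single surviving end
    node holds the complete set of MLCS strings. A classical
    dynamic-programming score table with exhaustive traceback, a
    brute-force enumerator and a dominant-point (Minima) baseline are
    included for cross-verification, together with FASTA input/output
    and a seeded random sequence-set generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Rcpp,
    Biostrings,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sequences-io.R'
    'successor-table.R'
    'leveled-dag.R'
    'oracles.R'
    'dominant.R'
    'cli.R'
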