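Package: otindex
Title: Linear Indexing of Suffixes and Paths Under Suffix Tree Internal Nodes
Version: 0.1.0
Authors@R:
    person("Index", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds annotated suffix trees with suffix links, derives the
    OSHR tree (reversed suffix links over internal nodes), and enumerates
    the base suffixes and base paths of every internal node by several
    interchangeable algorithms, including linear-time ones driven by
    reference leaf and reference internal nodes.  On top of the base
    suffixes it constructs the OT index: a global permutation of suffix
    positions with per-node offset pairs from which the full suffix set of
    any internal node can be read off as a contiguous slice.  Includes a
    FASTA/raw-text preprocessor, a deterministic synthetic string
    generator, an algorithm-equivalence harness, an operation-count
    scaling study, and a small command line interface with an exact
    pattern matching demo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
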