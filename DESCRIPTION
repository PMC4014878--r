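Package: phyloPuzzle
Title: Tree-Guided Game Scoring and Crowd-Style Refinement of Multiple
    Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the computational core of a crowd-computing approach
    to multiple sequence alignment refinement. Alignments are scored by
    reconstructing ancestral sequences with a per-column Fitch parsimony
    variant that treats the gap as a fifth character, then summing
    affine-gap scores of the induced pairwise alignments over all edges of
    a rooted binary phylogenetic tree, with terminal gaps free. On top of
    the scorer the package provides sliding-window extraction of short
    "casual" and long "expert" puzzle blocks from a parent alignment,
    admission, ranking and reinsertion of candidate block realignments, a
    stochastic hill-climbing solver that stands in for human players, and a
    seeded simulator of trees and gapped alignments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
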