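Package: mitotdrl
Title: Tandem Duplication-Random Loss Inference for Mitochondrial Gene Orders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing vertebrate mitochondrial genome rearrangements
    under the tandem duplication-random loss (TDRL) model. Parses mitogenome
    annotations from GenBank flat files or plain coordinate tables, computes
    intergenic spacers and overlaps on the circular genome, encodes gene-order
    windows as integer permutations against the typical vertebrate order, tests
    whether a rearrangement is explainable by a single tandem
    duplication-random loss event, localises the minimal duplicated interval
    and the survivor bipartition, predicts pseudogene-remnant sites and scores
    their correspondence with observed intergenic spacers. Also includes a
    combinatorial stem-loop (inverted repeat) scanner for locating putative
    light-strand replication origins, and a seeded simulator generating TDRL
    events, coordinate tables and sequences with planted hairpins for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
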