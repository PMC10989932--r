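Package: phylokit
Title: Supermatrix Construction and Tree-Based Diagnostics for Multilocus Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for organelle-scale multilocus phylogenetics: parses
    GenBank flat files and extracts genes with alias-based name unification and
    RefSeq-aware deduplication; builds codon-aware concatenated supermatrices
    with '?'-filled missing genes and partition (charset) emission; and computes
    a panel of tree-based diagnostics including patristic distance matrices,
    long-branch scores, spurious-species detection, treeness, relative
    composition variability (RCV), signal-to-noise ratio, substitution
    saturation regression, evolution rate, and root-to-tip branch lengths.
    Includes deterministic synthetic-data generators (Yule trees, Jukes-Cantor
    sequence evolution, toy GenBank records) and writers for iTOL bar datasets
    and partition files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
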