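---
title: "phylokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylokit)
```

## Scope

phylokit covers the bespoke computational core of an organelle-scale
multilocus phylogenetics workflow: preparing per-gene sequence sets from
GenBank records, assembling them into a partitioned supermatrix, and
screening alignments and trees with a panel of tree-based diagnostics.
External heavy lifting — alignment (MAFFT/MACSE), trimming, model selection
and tree inference — is deliberately out of scope: phylokit produces and
consumes the files those tools exchange.

## Data preparation

**Deduplication.** Mitogenomes that passed RefSeq screening circulate under
two accessions with an identical sequence. `deduplicate_records()` groups
records by their full genome sequence (case-insensitive) and keeps one per
group, preferring an `NC_` (RefSeq) accession, else the first encountered.
The rule is deterministic, idempotent, and `kept + removed` always
partitions the input.

**Name unification.** GenBank gene naming is submitter-dependent (*COX1*,
*COI*, *COXI* are the same gene). Lookup normalises a raw name to lowercase
with punctuation and whitespace stripped, consults the `/gene` qualifier
first and `/product` second, and maps through an alias table
(old name → new name). The bundled table covers the standard animal
mitochondrial complement (13 protein-coding genes, 2 rRNAs, 22 tRNAs) with
common synonyms; it is a curated starting point, not an authority — users
can replace it with a 2-column TSV, and every unmatched raw name is passed
through normalised and tallied in `name_for_unification.tsv` so the table
can be refined iteratively.

**Extraction and translation.** Feature intervals are concatenated in
order and reverse-complemented on the minus strand. CDS features translate
under their `/transl_table` when annotated, else the caller's code table;
the terminal stop is stripped. Codons carrying IUPAC ambiguity codes
translate normally only when every expansion agrees on the amino acid
(synonymous ambiguity); otherwise they yield `X`. This is conservative on
purpose: a wrong confident residue is worse than an explicit unknown.
Genetic-code tables are the NCBI tables (1, 2, 3, 4, 5, 9, 11, 13, 14
bundled); table 9 (echinoderm/flatworm mitochondrial: AAA→Asn, AGA→Ser,
TGA→Trp) is the one exercised most by the test fixtures.

## Supermatrix assembly

Concatenation matches taxa across genes by exact label equality — labels
are generated by `make_taxon_label()` and must round-trip unchanged, so no
fuzzy matching is attempted. A taxon absent from a gene receives a block of
`?` of that gene's width; gaps *within* present genes remain `-`. The two
characters deliberately encode different facts: `-` is an inferred indel,
`?` is absence of data. Partition charsets are contiguous, 1-based and
inclusive, in the insertion order of the gene list (user-controllable);
codon-position charsets use the `start-end\3` stride notation, with
explicit per-position partitions available through
`codon_partition_scheme()`.

Frameshift sanitisation replaces `!` with `?` everywhere, and `*` with `?`
only in nucleotide data: in amino-acid data `*` is a legitimate stop, and
the refinement tools that emit frameshift marks do so in their nucleotide
output.

Back-translation verifies, residue by residue, that each taxon's unaligned
CDS translates to its aligned row with gaps removed (one terminal stop
codon on the CDS is tolerated and dropped), then maps every residue to its
source codon, `-` to `---` and `?`/`X` to `???` (the source codon is still
consumed for `X`). A mismatch is an error naming the taxon and the first
discordant position — silent repair would defeat the point of a codon-aware
pipeline.

## Tree-based diagnostics

All statistics operate on edge-weighted trees with branch lengths in
expected substitutions per site. A statistic that needs lengths raises an
error naming the offending edge rather than assuming zero.

**Patristic distances.** `d(i,j)` is the sum of branch lengths on the
unique path between leaves i and j, computed from node depths and most
recent common ancestors. The matrix is symmetric, has a zero diagonal,
satisfies the four-point condition, and is invariant to rooting. The test
suite checks it against a brute-force parent-chain path-sum oracle and an
independent library implementation.

**Long-branch scores.** For taxon i,

$$LB_i = \left(\frac{\overline{PD}_i}{\overline{PD}_{all}} - 1\right)\times 100,$$

where $\overline{PD}_i$ is the mean patristic distance from i to the other
n−1 taxa and $\overline{PD}_{all}$ the mean over all n(n−1)/2 pairs. The
scores are percent deviations, rooting-invariant, and sum to zero
algebraically — the suite verifies the identity numerically to 1e-9 over
1000 random trees. The "overall" summary reports the mean, sample standard
deviation (n−1 denominator), minimum and maximum of the per-taxon scores;
the standard deviation is the heterogeneity-style summary.

**Spurious species.** A taxon is flagged when its terminal branch is *at
least* (≥) `threshold` times the median of all branch lengths (terminal and
internal; a root stem annotation is excluded). The default threshold is 20;
there is no principled universal value, so the parameter is exposed.

**Treeness, RCV, signal-to-noise.** Treeness is the internal fraction of
total branch length. Edges are classified on the *unrooted* representation:
a degree-2 root's two edges are the two halves of one unrooted edge, and
counting the half above an outgroup tip as "internal" would make treeness
depend on rooting. With this convention treeness, like the other
tree-statistics panel members, is rooting-invariant. RCV is

$$RCV = \sum_i \sum_j \frac{|c_{ij} - \bar c_i|}{n\,t},$$

with $c_{ij}$ the count of state i in taxon j, $\bar c_i$ the mean count
over taxa, n the number of taxa and t the alignment length. The $c_{ij}$
are weighted *counts*, not proportions — the formula's n·t denominator
self-normalises. Degenerate codes contribute fractionally (Y = ½C + ½T,
D = ⅓A + ⅓G + ⅓T, N = ¼ each; for proteins B = ½D + ½N, Z = ½E + ½Q,
J = ½I + ½L, X = 1/20 each); gaps and `?` contribute nothing, but t counts
every column. Per-taxon values use the additive decomposition
$RCV_j = \sum_i |c_{ij} - \bar c_i|/(n t)$, so they sum to the total.
Signal-to-noise is treeness/RCV and errors cleanly at RCV = 0.

**Pairwise differences and saturation.** The pairwise difference is the
uncorrected p-distance with pairwise deletion: compared sites are the
columns where *both* taxa carry an unambiguous state, and ambiguity codes
are excluded entirely here even though they contribute fractional weights
to composition — each convention matches the intent of its own formula
(distance estimation versus composition accounting). The saturation
regression fits observed difference (y) on patristic distance (x). The
default is ordinary least squares with an intercept; a through-origin fit
is available, with the no-intercept $R^2 = 1 - SS_{res}/\sum y^2$ so the
value stays in [0, 1]. A zero-variance response reports $r^2 = 0$ (the fit
explains nothing). Under multiple substitution the observed difference
plateaus while patristic distance keeps growing, so saturated data show a
depressed slope and $r^2$.

**Evolution rate.** Total branch length divided by the number of terminal
nodes; linear in branch-length scale, and intended for ranking single-gene
trees from fast- to slow-evolving.

**Root-to-tip lengths** are the one rooting-*dependent* quantity in the
panel. `set_outgroup()` places the new root at the midpoint of the broken
attachment edge (equal-split rule, matching common toolkit behaviour), and
root-to-tip values inherit that convention; patristic distances do not.

## Synthetic data

The generators exist so that the whole package builds and tests with no
downloads, and their defaults are fixed study conditions, not tuning knobs.

* `simulate_yule_tree(n, birth = 1, scale = 1)` draws a Yule labelled
  topology (uniform random joins) and i.i.d. exponential branch lengths
  with rate `birth`, multiplied by `scale` after simulation so that the
  same seed at double scale gives exactly doubled lengths.
* `evolve_alignment()` implements Jukes–Cantor evolution: per edge of
  length b each site changes with probability ¾(1 − e^(−4b/3)), uniformly
  to one of the other three bases. The closed-form expected pairwise
  difference at patristic distance d, ¾(1 − e^(−4d/3)), is the oracle the
  tests compare against (within three binomial standard errors at 10,000
  sites).
* `genbank_fixture()` lays genes head-to-tail on a synthetic genome and
  emits a valid flat-file record; the extractor must recover every input
  sequence exactly, including minus-strand genes.

What the generators do *not* emulate: indels, rate heterogeneity across
sites, compositional bias, model misspecification, annotation errors.
Passing tests therefore demonstrate correctness of the computations, not
robustness of the statistics on messy empirical data.

Problem sizes in the default test run were chosen to keep the suite fast
while leaving no property under-sampled: 1000 trees (n = 4..64) for the
long-branch identity, 100–200 random fixtures for round-trip and oracle
checks, 10,000 sites for the Jukes–Cantor expectation, 500 random CDS for
the back-translation inverse.

* The low-divergence slope-recovery condition uses branch scale 0.05
  (pairwise distances ≲ 0.1 substitutions/site), where the Jukes–Cantor
  curve is still near-linear and the regression should recover a slope
  near 1; the saturated condition multiplies the same branch lengths by 10.

## Other design decisions

* Newick dialect: single-quoted labels supported; underscores in unquoted
  labels are preserved verbatim (labels of the form `Genus_species_ACC`
  must survive a round trip); bracketed comments stripped; internal labels
  carried as support annotations and ignored by statistics.
* Unrooting merges the two root edges (lengths summed) under the
  first-listed root child — deterministic from input order.
* Polytomy resolution ladderizes children left-to-right in input order,
  inserting edges of a caller-chosen length (default 0, which preserves
  the patristic matrix exactly).
* PHYLIP I/O uses the relaxed sequential dialect (labels up to whitespace):
  strict 10-character names would truncate `organism_accession` labels.
* Alphabet auto-detection calls a matrix nucleotide when ≥ 90% of its
  non-gap characters are in {A, C, G, T, N}; pass `alphabet=` explicitly
  for edge cases (e.g. a single degenerate-heavy column).
* CSV output uses 6 significant digits by default (adjustable); identical
  inputs produce byte-identical outputs, which the suite asserts.

## Limitations

* NeXML/PhyloXML tree formats are not parsed (their dialects are not
  pinned down by the upstream workflow this package mirrors).
* Only Jukes–Cantor simulation is provided — sufficient to exercise the
  saturation and composition properties, not a general simulator.
* The spurious-species median and the LB summary are descriptive screens,
  not hypothesis tests; thresholds are conventions to be reported, not
  p-values.
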