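# phylokit

Supermatrix construction and tree-based diagnostics for multilocus
phylogenetics.

Multilocus (and especially organelle-genome) phylogenetics is a pipeline
problem: genes must be pulled out of GenBank records whose annotations use
inconsistent names, redundant RefSeq/INSDC record pairs must be collapsed,
per-gene alignments must be concatenated into a partitioned supermatrix
with missing genes marked, and the resulting alignments and trees should be
screened for the pathologies that mislead tree inference — long-branch
attraction, compositional bias, substitution saturation and rogue taxa.
phylokit implements that bespoke core as a plain R library plus a thin
command-line tool, for systematists assembling mitogenome-scale datasets
and for anyone who needs the tree-screening statistics on their own trees.
The surrounding heavy machinery (MAFFT, trimming tools, ModelFinder,
IQ-TREE, MrBayes) is out of scope on purpose: phylokit reads and writes the
files those programs exchange.

## What it computes

For a tree with branch lengths and leaves *1..n*, with patristic distance
*d(i,j)* the sum of branch lengths on the *i–j* path:

* **Long-branch score**: LB_i = (PD̄_i / PD̄_all − 1) × 100, where PD̄_i is
  the mean patristic distance from taxon *i* to the others and PD̄_all the
  mean over all pairs. Percent deviation from the tree-wide average; the
  scores sum to zero and do not depend on the root.
* **Spurious (rogue) species**: terminal branch ≥ *threshold* × median of
  all branch lengths (default threshold 20).
* **Treeness**: internal branch length / total branch length, computed on
  the unrooted representation.
* **RCV** (relative composition variability):
  RCV = Σ_i Σ_j |c_ij − c̄_i| / (n·t), with degenerate bases counted
  fractionally (Y = ½C + ½T, D = ⅓A + ⅓G + ⅓T, ...).
* **Signal-to-noise ratio**: treeness / RCV.
* **Substitution saturation**: regression of pairwise difference
  (p-distance, pairwise deletion) on patristic distance; saturated data
  show depressed slope and r².
* **Evolution rate**: total branch length / number of terminal nodes.
* Plus patristic and p-distance matrices, root-to-tip lengths, outgroup
  rooting (equal-split rule), unrooting and deterministic polytomy
  resolution.

Data preparation: GenBank flat-file parsing, RefSeq-preferring
deduplication, alias-based gene-name unification (bundled mitochondrial
table, user-replaceable), code-table-aware CDS translation (NCBI tables 1,
2, 3, 4, 5, 9, 11, 13, 14), codon-position selection, `?`-filled
concatenation with NEXUS/RAxML partition emission, codon-aware
back-translation, frameshift-mark sanitisation, and iTOL simple-bar
dataset output. Deterministic generators (Yule trees, Jukes–Cantor
evolution, toy GenBank records) make the whole package testable offline.

## Worked example

```r
library(phylokit)

tr <- parse_newick("((A:1,B:2):1,(C:3,D:4):2);")
lb_scores(tr)
#> <lb_report> 4 taxa, mean PD 7
#>  taxon  mean_pd         lb
#>      A 6.000000 -14.285714
#>      B 6.666667  -4.761905
#>      C 7.333333   4.761905
#>      D 8.000000  14.285714
```

Taxon D's average distance to the others (8) sits 14.3% above the
tree-wide mean pairwise distance (7), so D is the strongest long-branch
candidate; the four scores sum to zero by construction.

```r
treeness(tr)
#> [1] 0.2307692
evolution_rate(tr)
#> [1] 3.25
spurious_species(tr, threshold = 1.5)$flagged
#> [1] "C" "D"
```

Only 3/13 of the tree's length lies on internal branches (weak internal
signal); the rate is 13/4 substitutions/site per terminal; at a threshold
of 1.5 the terminals of C (3) and D (4) are at least 1.5× the median
branch length (2) and are flagged — at the default threshold of 20,
nothing is.

```r
aln <- aln_matrix(c(A = "AAAA", B = "TTTT", C = "AAAA", D = "TTTT"))
signal_to_noise(tr, aln)
#> $signal_to_noise
#> [1] 0.2307692
#> $treeness
#> [1] 0.2307692
#> $rcv
#> [1] 1
```

Two maximally divergent base compositions give the maximal RCV of 1, so
the signal-to-noise ratio collapses to the treeness value.

```r
res <- concatenate(list(cox1 = aln_matrix(c(A = "AAA", B = "CCC")),
                        rrnL = aln_matrix(c(A = "GG", C = "TT"))))
res$matrix
#>       A       B       C
#> "AAAGG" "CCC??" "???TT"
cat(write_partition_scheme(res$scheme, "nexus_sets"))
#> begin sets;
#>   charset cox1 = 1-3;
#>   charset rrnL = 4-5;
#> end;
```

Taxa missing a gene are padded with `?` (missing data), not `-` (indel),
and the charsets record each gene's 1-based column range.

The same operations are scriptable from a shell via the installed CLI,
e.g.:

```sh
phylokit treestats --analysis lb --tree t.nwk --out lb_results
phylokit concat --genes cox1.fasta rrnL.fasta --out concat --split-codon 12 --pcg cox1
```

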