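#' Simulate a Yule (pure-birth) tree
#'
#' Builds a rooted, strictly bifurcating topology by the Yule splitting
#' process (uniform random joins over labelled histories) with leaves
#' labelled `T1..Tn`, then draws every branch length independently from an
#' exponential distribution with rate `birth` and multiplies it by `scale`.
#' With the same `seed`, `scale = 2` yields exactly double the lengths of
#' `scale = 1`. All randomness is governed by `seed`.
#'
#' @param n Number of leaves (>= 2).
#' @param birth Birth rate (exponential rate of branch lengths, per
#'   substitutions/site).
#' @param scale Multiplier applied to all branch lengths after simulation.
#' @param seed Optional integer seed (set for reproducibility).
#' @return A rooted bifurcating `phylo` tree with `2n - 2` edges.
#' @export
simulate_yule_tree <- function(n, birth = 1, scale = 1, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("a tree needs at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  # coalescent-style uniform joins give the Yule labelled topology
  nodes <- as.list(paste0("T", seq_len(n)))
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    joined <- paste0("(", nodes[[pick[1]]], ",", nodes[[pick[2]]], ")")
    nodes <- c(nodes[-pick], list(joined))
  }
  tree <- ape::read.tree(text = paste0(nodes[[1]], ";"))
  n_edge <- nrow(tree$edge)
  tree$edge.length <- stats::rexp(n_edge, rate = birth) * scale
  tree
}

#' Evolve a gap-free alignment along a tree under Jukes-Cantor
#'
#' The root sequence is uniform over `{A, C, G, T}`. Along every edge of
#' length b each site changes with probability `3/4 * (1 - exp(-4 b / 3))`
#' (the Jukes-Cantor transition probability, b in expected
#' substitutions/site); a changing site picks one of the three other bases
#' uniformly. The expected pairwise difference between two leaves at
#' patristic distance d is therefore `3/4 * (1 - exp(-4 d / 3))`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param length Number of sites.
#' @param seed Optional integer seed.
#' @return A nucleotide [aln_matrix()] with one row per leaf.
#' @export
evolve_alignment <- function(tree, length, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  check_branch_lengths(tree)
  length <- as.integer(length)
  if (length < 1L) stop("alignment length must be positive")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  seqs <- vector("list", n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample(bases, length, replace = TRUE)
  for (k in rev(seq_len(nrow(po$edge)))) {   # preorder traversal
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]; b <- po$edge.length[k]
    p_change <- 0.75 * (1 - exp(-4 * b / 3))
    child <- seqs[[par]]
    hit <- which(stats::runif(length) < p_change)
    if (length(hit)) {
      # substitute uniformly among the three other bases
      shift <- sample.int(3L, length(hit), replace = TRUE)
      old <- match(child[hit], bases)
      child[hit] <- bases[((old - 1L + shift) %% 4L) + 1L]
    }
    seqs[[ch]] <- child
  }
  rows <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                 character(1))
  aln_matrix(rows, labels = tree$tip.label, alphabet = "nucleotide")
}

#' Emit a toy GenBank record
#'
#' Lays the supplied genes head-to-tail on a synthetic genome and writes a
#' syntactically valid GenBank flat-file record that [read_genbank()] parses
#' and [extract_genes()] recovers exactly. Minus-strand genes are stored
#' reverse-complemented in the genome with a `complement(..)` location.
#'
#' @param genes A data frame with columns `name`, `seq` (forward-orientation
#'   nucleotides), `kind` (`"CDS"`, `"tRNA"` or `"rRNA"`) and optionally
#'   `strand` (`"+"`/`"-"`, default `"+"`).
#' @param organism Organism name.
#' @param accession Accession string (use an `NC_` prefix for a RefSeq-like
#'   record).
#' @param lineage Character vector of lineage ranks.
#' @param transl_table NCBI code table id written on CDS features.
#' @param spacer Number of `A` bases inserted between genes.
#' @return The GenBank record as a single text string.
#' @export
genbank_fixture <- function(genes, organism = "Synthia exempli",
                            accession = "NC_900001",
                            lineage = c("Eukaryota", "Synthetica"),
                            transl_table = 9L, spacer = 3L) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$strand)) genes$strand <- "+"
  genome <- ""
  feats <- character(0)
  for (i in seq_len(nrow(genes))) {
    if (nzchar(genome)) genome <- paste0(genome, strrep("A", spacer))
    s <- toupper(genes$seq[i])
    start <- nchar(genome) + 1L
    end <- nchar(genome) + nchar(s)
    stored <- if (genes$strand[i] == "-") reverse_complement(s) else s
    genome <- paste0(genome, stored)
    loc <- if (genes$strand[i] == "-") {
      sprintf("complement(%d..%d)", start, end)
    } else sprintf("%d..%d", start, end)
    key <- genes$kind[i]
    feats <- c(feats,
      sprintf("     %-16s%s", key, loc),
      sprintf("                     /gene=\"%s\"", genes$name[i]))
    if (key == "CDS") {
      feats <- c(feats,
        sprintf("                     /transl_table=%d", transl_table))
    }
  }
  origin <- format_origin(genome)
  paste0(
    sprintf("LOCUS       %s %d bp    DNA     circular     01-JAN-2026\n",
            accession, nchar(genome)),
    sprintf("DEFINITION  %s mitochondrion, synthetic test record.\n", organism),
    sprintf("ACCESSION   %s\n", accession),
    sprintf("VERSION     %s.1\n", accession),
    "SOURCE      mitochondrion ", organism, "\n",
    sprintf("  ORGANISM  %s\n", organism),
    sprintf("            %s.\n", paste(lineage, collapse = "; ")),
    "FEATURES             Location/Qualifiers\n",
    sprintf("     source          1..%d\n", nchar(genome)),
    sprintf("                     /organism=\"%s\"\n", organism),
    paste(feats, collapse = "\n"), "\n",
    "ORIGIN\n",
    origin,
    "//\n"
  )
}

format_origin <- function(genome) {
  n <- nchar(genome)
  starts <- seq(1L, n, 60L)
  lines <- vapply(starts, function(st) {
    chunk <- substr(genome, st, min(st + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    sprintf("%9d %s", st, tolower(paste(groups, collapse = " ")))
  }, character(1))
  paste0(paste(lines, collapse = "\n"), "\n")
}
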