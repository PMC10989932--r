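# Independent oracles used to cross-check the implementation.

# distance from node i to each of its ancestors, by walking parent chains
anc_dists <- function(tree, i) {
  out <- numeric(0)
  d <- 0
  node <- i
  repeat {
    k <- match(node, tree$edge[, 2])
    if (is.na(k)) break
    d <- d + tree$edge.length[k]
    node <- tree$edge[k, 1]
    out[as.character(node)] <- d
  }
  out
}

# brute-force patristic matrix: minimal summed parent-chain distance through
# any shared ancestor
oracle_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  A <- lapply(seq_len(n), function(i) anc_dists(tree, i))
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      common <- intersect(names(A[[i]]), names(A[[j]]))
      D[i, j] <- D[j, i] <- min(A[[i]][common] + A[[j]][common])
    }
  }
  D
}

# four-point condition: for every sampled quadruple the largest of the three
# pairwise sums is attained at least twice
check_four_point <- function(d, n_quadruples = 50, tol = 1e-9) {
  n <- nrow(d)
  if (n < 4) return(TRUE)
  for (q in seq_len(n_quadruples)) {
    idx <- sample.int(n, 4)
    s <- sort(c(d[idx[1], idx[2]] + d[idx[3], idx[4]],
                d[idx[1], idx[3]] + d[idx[2], idx[4]],
                d[idx[1], idx[4]] + d[idx[2], idx[3]]))
    if (s[3] - s[2] > tol * max(1, s[3])) return(FALSE)
  }
  TRUE
}

random_fixture_tree <- function(n, seed) {
  simulate_yule_tree(n, birth = 2, scale = 1, seed = seed)
}

random_fixture_aln <- function(n_taxa, t, seed, alphabet = "nucleotide") {
  set.seed(seed)
  chars <- if (alphabet == "nucleotide") c("A", "C", "G", "T", "-") else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  }
  rows <- vapply(seq_len(n_taxa), function(i) {
    paste(sample(chars, t, replace = TRUE), collapse = "")
  }, character(1))
  aln_matrix(rows, labels = paste0("T", seq_len(n_taxa)), alphabet = alphabet)
}

# random gap-free CDS ending without internal stops, under a given code
random_cds <- function(n_codons, code, seed) {
  set.seed(seed)
  sense <- setdiff(names(code$codons), code$stops)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
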