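#' @title Tree-based diagnostics
#' @description Internal helpers shared by the tree statistics.
#' @name treestats-internal
#' @keywords internal
NULL

check_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad)) {
    child <- tree$edge[bad[1], 2]
    lab <- if (child <= ape::Ntip(tree)) tree$tip.label[child] else {
      sprintf("internal node %d", child)
    }
    stop(sprintf("missing branch length on the edge above %s", lab))
  }
  invisible(TRUE)
}

# depth (path length from the base node) of every node
node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  lens <- po$edge.length
  # preorder = reversed postorder
  for (k in rev(seq_len(nrow(edge)))) {
    depth[edge[k, 2]] <- depth[edge[k, 1]] + lens[k]
  }
  depth
}

#' Patristic (tip-to-tip) distance matrix
#'
#' The patristic distance between two leaves is the sum of branch lengths on
#' the unique path connecting them. The matrix is symmetric with a zero
#' diagonal and is invariant to (re)rooting.
#'
#' @param tree A `phylo` tree with branch lengths on every edge.
#' @return A symmetric numeric matrix with taxon dimnames and attribute
#'   `metric = "patristic"`.
#' @examples
#' patristic_matrix(parse_newick("((A:1,B:2):1,(C:3,D:4):2);"))["A", "D"] # 8
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  check_branch_lengths(tree)
  n_tip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  m <- ape::mrca(tree)
  tip_depth <- depth[seq_len(n_tip)]
  d <- outer(tip_depth, tip_depth, "+") - 2 * matrix(depth[m], n_tip, n_tip)
  diag(d) <- 0
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  attr(d, "metric") <- "patristic"
  d
}

#' Root-to-tip path lengths
#'
#' Sum of branch lengths from each leaf to the root. Requires a rooted tree
#' (root with exactly two children); root an unrooted tree first with
#' [set_outgroup()]. Note that after outgroup rooting the values depend on
#' the equal-split placement of the root on the broken edge. On an
#' ultrametric tree all values are equal.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Named numeric vector, one length per leaf.
#' @export
root_to_tip_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!is_rooted_tree(tree)) {
    stop("tree is unrooted; root it first (e.g. with set_outgroup())")
  }
  check_branch_lengths(tree)
  depth <- node_depths(tree)
  stats::setNames(depth[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Long-branch scores
#'
#' For each taxon i, `LB_i = (PDbar_i / PDbar_all - 1) * 100`, where
#' `PDbar_i` is the mean patristic distance from i to every other taxon and
#' `PDbar_all` is the mean over all unordered taxon pairs. The score is the
#' percent deviation of a taxon's average distance from the tree-wide
#' average; large positive scores flag taxa prone to long-branch attraction.
#' The scores are rooting-invariant and sum to zero over the taxa (an
#' algebraic identity).
#'
#' @param tree A `phylo` tree (>= 3 leaves) with branch lengths.
#' @return An `lb_report`: `scores` (data frame `taxon`, `mean_pd`, `lb`),
#'   `mean_pd_all`, and `summary` (mean, sample standard deviation, min,
#'   max of the scores).
#' @export
lb_scores <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 3L) stop("long-branch scores need at least 3 leaves")
  d <- patristic_matrix(tree)
  mean_pd <- rowSums(d) / (n - 1)
  mean_all <- sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
  if (mean_all == 0) stop("mean patristic distance is zero; scores undefined")
  lb <- (mean_pd / mean_all - 1) * 100
  structure(
    list(
      scores = data.frame(taxon = rownames(d), mean_pd = unname(mean_pd),
                          lb = unname(lb), stringsAsFactors = FALSE),
      mean_pd_all = mean_all,
      summary = c(mean = mean(lb), sd = stats::sd(lb),
                  min = min(lb), max = max(lb))
    ),
    class = "lb_report"
  )
}

#' @export
print.lb_report <- function(x, ...) {
  cat(sprintf("<lb_report> %d taxa, mean PD %.6g\n",
              nrow(x$scores), x$mean_pd_all))
  print(utils::head(x$scores, 10L), row.names = FALSE)
  invisible(x)
}

#' Flag spurious (rogue) species by terminal branch length
#'
#' A taxon is flagged when its terminal branch is at least `threshold` times
#' the median of all branch lengths across the tree (terminal and internal
#' edges; a root stem, if annotated, is excluded). The comparison is `>=`
#' ("at least"), so a terminal branch exactly at the cutoff is flagged.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param threshold Positive multiplier of the median (default 20).
#' @return A list: `flagged` (character vector), `median_length`,
#'   `terminal_lengths` (named numeric), `threshold`.
#' @export
spurious_species <- function(tree, threshold = 20) {
  stopifnot(inherits(tree, "phylo"))
  if (threshold <= 0) stop("threshold must be positive")
  check_branch_lengths(tree)
  med <- stats::median(tree$edge.length)
  if (med == 0) stop("degenerate tree: median branch length is zero")
  tip_edge <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
  term <- stats::setNames(tree$edge.length[tip_edge], tree$tip.label)
  flagged <- names(term)[term >= threshold * med]
  list(flagged = flagged, median_length = med, terminal_lengths = term,
       threshold = threshold)
}

#' Treeness (stemminess)
#'
#' The fraction of the tree's total branch length found on internal edges
#' (edges whose child is not a leaf). Values near 0 indicate that most
#' change happened on terminal branches (weak internal signal). Edges are
#' classified on the unrooted representation (a degree-2 root's two edges
#' count as the single merged edge they represent), so the value is
#' invariant to rooting.
#'
#' @param tree A `phylo` tree with branch lengths and positive total length.
#' @return A number in `[0, 1]`.
#' @examples
#' treeness(parse_newick("((A:1,B:2):1,(C:3,D:4):2);"))  # 3/13
#' @export
treeness <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  check_branch_lengths(tree)
  if (ape::Ntip(tree) >= 3L && is_rooted_tree(tree)) tree <- ape::unroot(tree)
  total <- sum(tree$edge.length)
  if (total <= 0) stop("total branch length is zero")
  internal <- tree$edge[, 2] > ape::Ntip(tree)
  sum(tree$edge.length[internal]) / total
}

# ---- composition ---------------------------------------------------------

# weight of each observed character over the base states, with IUPAC
# degenerate codes contributing fractional counts
composition_weights <- function(alphabet) {
  if (alphabet == "nucleotide") {
    states <- c("A", "C", "G", "T")
    w <- matrix(0, nrow = length(states), ncol = 0,
                dimnames = list(states, NULL))
    add <- function(chr, parts) {
      col <- stats::setNames(rep(0, length(states)), states)
      col[parts] <- 1 / length(parts)
      w <<- cbind(w, col)
      colnames(w)[ncol(w)] <<- chr
    }
    exp <- iupac_nt_expansion()
    for (chr in names(exp)) add(chr, exp[[chr]])
    w
  } else {
    states <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    w <- matrix(0, nrow = length(states), ncol = 0,
                dimnames = list(states, NULL))
    add <- function(chr, parts, wt = 1 / length(parts)) {
      col <- stats::setNames(rep(0, length(states)), states)
      col[parts] <- wt
      w <<- cbind(w, col)
      colnames(w)[ncol(w)] <<- chr
    }
    for (chr in states) add(chr, chr)
    add("B", c("D", "N")); add("Z", c("E", "Q")); add("J", c("I", "L"))
    add("X", states)
    w
  }
}

#' Weighted character-composition profile of an alignment
#'
#' Counts character-state occurrences per taxon, expanding IUPAC degenerate
#' codes fractionally: for nucleotides Y counts as 1/2 C + 1/2 T, D as 1/3
#' A + 1/3 G + 1/3 T, N as 1/4 each, and so on; for amino acids B = 1/2 D +
#' 1/2 N, Z = 1/2 E + 1/2 Q, J = 1/2 I + 1/2 L, X = 1/20 each. Gaps, `?`
#' and other non-state characters contribute nothing. `t` is the full
#' alignment length (gap-containing columns included).
#'
#' @param aln An [aln_matrix()].
#' @return A `composition_profile`: `states`, `counts` (states x taxa
#'   matrix of weighted counts), `mean_counts`, `n`, `t`.
#' @export
composition_profile <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  w <- composition_weights(aln_alphabet(aln))
  counts <- vapply(aln, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    tab <- table(factor(chars, levels = colnames(w)))
    as.numeric(w %*% as.numeric(tab))
  }, numeric(nrow(w)))
  rownames(counts) <- rownames(w)
  structure(
    list(states = rownames(w), counts = counts,
         mean_counts = rowMeans(counts),
         n = length(aln), t = aln_ncol(aln)),
    class = "composition_profile"
  )
}

#' Relative composition variability (RCV)
#'
#' `RCV = sum_i sum_j |c_ij - cbar_i| / (n * t)` where `c_ij` is the
#' (degenerate-weighted) count of state i in taxon j, `cbar_i` the mean
#' count of state i over the n taxa, and t the alignment length. RCV is 0
#' iff all taxa share an identical weighted composition; larger values mean
#' stronger compositional bias ("noise"). The per-taxon values
#' `RCV_j = sum_i |c_ij - cbar_i| / (n * t)` decompose the total additively
#' (`sum_j RCV_j = RCV`).
#'
#' @param aln An [aln_matrix()] with at least 2 taxa.
#' @return A list: `rcv` (overall) and `per_taxon` (named numeric).
#' @export
rcv <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  if (length(aln) < 2L) stop("RCV needs at least 2 taxa")
  prof <- composition_profile(aln)
  dev <- abs(prof$counts - prof$mean_counts)
  per_taxon <- colSums(dev) / (prof$n * prof$t)
  list(rcv = sum(per_taxon), per_taxon = per_taxon)
}

#' Signal-to-noise ratio (treeness over RCV)
#'
#' @param tree A `phylo` tree whose leaves appear in the alignment.
#' @param aln The matching [aln_matrix()].
#' @return A list: `signal_to_noise`, `treeness`, `rcv`.
#' @export
signal_to_noise <- function(tree, aln) {
  missing <- setdiff(tree$tip.label, names(aln))
  if (length(missing)) {
    stop(sprintf("tree leaves absent from alignment: %s",
                 paste(missing, collapse = ", ")))
  }
  tn <- treeness(tree)
  r <- rcv(aln)$rcv
  if (r == 0) stop("RCV is zero: signal-to-noise ratio is undefined")
  list(signal_to_noise = tn / r, treeness = tn, rcv = r)
}

# ---- pairwise sequence statistics ---------------------------------------

unambiguous_states <- function(alphabet) {
  if (alphabet == "nucleotide") c("A", "C", "G", "T")
  else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' Pairwise sequence differences and identities
#'
#' For every taxon pair, the compared sites are the columns where both rows
#' carry an unambiguous character state (gaps, `?` and degenerate codes are
#' excluded pairwise). The pairwise difference is the fraction of compared
#' sites that mismatch (the uncorrected p-distance); identity is its
#' complement. Pairs with zero compared sites are flagged and carry `NA`.
#'
#' @param aln An [aln_matrix()] with at least 2 taxa.
#' @return A list: `p_distance` (symmetric matrix, attr `metric =
#'   "p_distance"`), `records` (data frame `taxon1`, `taxon2`, `compared`,
#'   `difference`, `identity`), `excluded_pairs` (rows with no compared
#'   sites).
#' @export
pairwise_sequence_stats <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  n <- length(aln)
  if (n < 2L) stop("pairwise statistics need at least 2 taxa")
  states <- unambiguous_states(aln_alphabet(aln))
  rows <- lapply(aln, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  ok <- lapply(rows, function(ch) ch %in% states)
  labs <- names(aln)
  d <- matrix(NA_real_, n, n, dimnames = list(labs, labs))
  diag(d) <- 0
  recs <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- ok[[i]] & ok[[j]]
      n_comp <- sum(comp)
      diff <- if (n_comp > 0L) mean(rows[[i]][comp] != rows[[j]][comp]) else NA_real_
      d[i, j] <- d[j, i] <- diff
      k <- k + 1L
      recs[[k]] <- data.frame(
        taxon1 = labs[i], taxon2 = labs[j], compared = n_comp,
        difference = diff, identity = 1 - diff, stringsAsFactors = FALSE
      )
    }
  }
  records <- do.call(rbind, recs)
  attr(d, "metric") <- "p_distance"
  list(p_distance = d, records = records,
       excluded_pairs = records[records$compared == 0L, , drop = FALSE])
}

#' Substitution-saturation regression
#'
#' Regresses the observed pairwise difference (y) on the patristic distance
#' (x) over all usable taxon pairs. Under substitution saturation multiple
#' hits accumulate: observed differences plateau while patristic distances
#' keep growing, which depresses both the slope and the r-squared of this
#' regression. The default fit is ordinary least squares with an intercept;
#' a through-origin fit is available (its r-squared uses the no-intercept
#' convention `1 - SSres / sum(y^2)`). When the response has zero variance
#' the coefficient of determination is reported as 0.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param aln The matching [aln_matrix()] (leaves must be present).
#' @param fit `"ols_intercept"` or `"through_origin"`.
#' @return A `saturation_result`: `pairs` (per-pair table with `patristic`,
#'   `difference`, `identity`, `compared`), `slope`, `intercept`, `r2`,
#'   `fit`, `n_pairs`.
#' @export
saturation_regression <- function(tree, aln,
                                  fit = c("ols_intercept", "through_origin")) {
  fit <- match.arg(fit)
  missing <- setdiff(tree$tip.label, names(aln))
  if (length(missing)) {
    stop(sprintf("tree leaves absent from alignment: %s",
                 paste(missing, collapse = ", ")))
  }
  pd <- patristic_matrix(tree)
  ps <- pairwise_sequence_stats(aln)
  recs <- ps$records
  recs <- recs[recs$taxon1 %in% tree$tip.label &
                 recs$taxon2 %in% tree$tip.label, , drop = FALSE]
  recs$patristic <- pd[cbind(recs$taxon1, recs$taxon2)]
  usable <- recs[recs$compared > 0L, , drop = FALSE]
  if (nrow(usable) < 3L) stop("fewer than 3 usable taxon pairs")
  x <- usable$patristic; y <- usable$difference
  if (stats::var(x) == 0) stop("zero variance in patristic distances")
  reg <- fit_saturation(x, y, fit)
  structure(
    list(pairs = usable[, c("taxon1", "taxon2", "patristic", "difference",
                            "identity", "compared")],
         slope = reg$slope, intercept = reg$intercept, r2 = reg$r2,
         fit = fit, n_pairs = nrow(usable)),
    class = "saturation_result"
  )
}

fit_saturation <- function(x, y, fit) {
  if (fit == "ols_intercept") {
    m <- stats::lm(y ~ x)
    ss_tot <- sum((y - mean(y))^2)
    ss_res <- sum(stats::residuals(m)^2)
    r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    list(slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]), r2 = r2)
  } else {
    m <- stats::lm(y ~ 0 + x)
    ss_tot <- sum(y^2)
    ss_res <- sum(stats::residuals(m)^2)
    r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
    list(slope = unname(stats::coef(m)[1]), intercept = 0, r2 = r2)
  }
}

#' @export
print.saturation_result <- function(x, ...) {
  cat(sprintf(
    "<saturation_result> %d pairs; slope %.4g, intercept %.4g, r2 %.4g (%s)\n",
    x$n_pairs, x$slope, x$intercept, x$r2, x$fit
  ))
  invisible(x)
}

#' Per-tree evolution rate
#'
#' Total branch length (internal plus terminal) divided by the number of
#' terminal nodes. Comparing this rate across single-gene trees separates
#' slow- from fast-evolving genes. Scaling all branch lengths by k scales
#' the rate by k.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A single number (substitutions/site per taxon).
#' @export
evolution_rate <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  check_branch_lengths(tree)
  sum(tree$edge.length) / ape::Ntip(tree)
}
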