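#' Parse a Newick tree string
#'
#' Parses a single Newick statement into an `ape::phylo` tree. Bracketed
#' comments (`[...]`) are stripped before parsing, single-quoted labels are
#' supported, and underscores in unquoted labels are preserved verbatim (they
#' are *not* converted to spaces), so labels of the form
#' `Genus_species_ACCESSION` survive a round trip. Internal node labels are
#' retained as support annotations; they play no role in any statistic.
#'
#' @param text A single Newick statement ending in `;`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,(C:3,D:4):2);")
#' sum(tr$edge.length)  # 13
#' @export
parse_newick <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("parse error: 'text' must be a single character string")
  }
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop("parse error at position 1: empty input")
  txt <- strip_newick_comments(text)
  check_parentheses(txt)
  if (!grepl(";\\s*$", txt)) {
    stop(sprintf("parse error at position %d: expected terminating ';'", nchar(txt)))
  }
  tr <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop(sprintf("parse error: %s", conditionMessage(e)))
  )
  if (is.null(tr)) stop("parse error: could not read a tree from input")
  if (inherits(tr, "multiPhylo")) {
    stop("parse error: more than one Newick statement supplied")
  }
  validate_tree(tr)
  tr
}

#' Write a tree as a Newick string
#'
#' Branch lengths are emitted with up to 10 significant digits, the statement
#' is `;`-terminated, and no line wrapping is applied.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file path; when given the string is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# remove non-nested [...] comment blocks (NHX-style annotations included)
strip_newick_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

check_parentheses <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("parse error at position %d: unbalanced ')'", i))
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "parse error at position %d: %d unclosed '('", nchar(txt), depth
    ))
  }
  invisible(TRUE)
}

validate_tree <- function(tree) {
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("parse error: empty leaf label")
  dup <- labs[duplicated(labs)]
  if (length(dup)) {
    stop(sprintf("parse error: duplicate leaf labels: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("invalid tree: negative branch length")
  }
  invisible(tree)
}

#' Is the tree in rooted (bifurcating-base) representation?
#'
#' A tree is treated as rooted when its base node has exactly two children;
#' a base of degree three or more denotes the unrooted representation.
#'
#' @param tree A `phylo` tree.
#' @return Logical scalar.
#' @export
is_rooted_tree <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  sum(tree$edge[, 1] == root) == 2L
}

#' Read trees from a file into a collection
#'
#' Reads one or more trees from a Newick file (one statement per tree) or a
#' NEXUS file (trees block; a translate table, when present, is honoured).
#' Entries are named after the file stem, suffixed with an index when the file
#' holds more than one tree.
#'
#' @param path Path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @return A named list of `phylo` trees of class `tree_collection`.
#' @export
read_tree_file <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  trees <- switch(format,
    newick = {
      txt <- readLines(path, warn = FALSE)
      txt <- strip_newick_comments(paste(txt, collapse = "\n"))
      suppressWarnings(
        tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
      )
    },
    nexus = tryCatch(ape::read.nexus(path), error = function(e) NULL)
  )
  if (is.null(trees)) stop(sprintf("no trees found in %s", path))
  if (inherits(trees, "phylo")) trees <- list(trees) else trees <- unclass(trees)
  if (length(trees) == 0L) stop(sprintf("no trees found in %s", path))
  lapply(trees, validate_tree)
  stem <- tools::file_path_sans_ext(basename(path))
  names(trees) <- if (length(trees) == 1L) stem else {
    paste0(stem, "_", seq_along(trees))
  }
  structure(trees, class = "tree_collection")
}

#' @export
print.tree_collection <- function(x, ...) {
  cat(sprintf("<tree_collection> %d tree(s): %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

# leaf set below every node (list indexed by node number)
descendant_leaf_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

#' Root a tree on an outgroup
#'
#' Reroots the tree so that one child of the (new, bifurcating) root subtends
#' exactly the outgroup taxa. The attachment edge broken by the new root is
#' split into two *equal* halves, one on each side of the root; root-to-tip
#' lengths depend on this equal-split convention. Leaf-to-leaf patristic
#' distances are unchanged by rerooting.
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of outgroup leaf labels. Must be separable
#'   from the remaining taxa by a single edge.
#' @return A rooted `phylo` tree (root with exactly two children).
#' @export
set_outgroup <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("outgroup must contain at least one taxon")
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) {
    stop(sprintf("unknown label(s): %s", paste(unknown, collapse = ", ")))
  }
  n_tip <- ape::Ntip(tree)
  if (length(taxa) >= n_tip) {
    stop("outgroup cannot include every leaf: no edge separates the split")
  }
  u <- if (is_rooted_tree(tree)) ape::unroot(tree) else tree
  sets <- descendant_leaf_sets(u)
  base <- n_tip + 1L
  comp <- setdiff(u$tip.label, taxa)
  separable <- any(vapply(seq_along(sets), function(i) {
    if (i == base) return(FALSE)
    s <- sets[[i]]
    setequal(s, taxa) || setequal(s, comp)
  }, logical(1)))
  if (!separable) {
    stop(sprintf(
      "outgroup is not separable by a single edge; offending split: {%s} | {%s}",
      paste(taxa, collapse = ","), paste(comp, collapse = ",")
    ))
  }
  r <- ape::root(u, outgroup = taxa, resolve.root = TRUE)
  # equal-split rule: the broken edge's length is shared half-and-half
  if (!is.null(r$edge.length)) {
    root <- ape::Ntip(r) + 1L
    idx <- which(r$edge[, 1] == root)
    total <- sum(r$edge.length[idx])
    r$edge.length[idx] <- total / 2
  }
  r
}

#' Unroot a tree
#'
#' Converts a rooted (bifurcating-base) tree into its unrooted representation:
#' the two former root edges are merged into a single edge whose length is
#' their sum, attached under the first-listed root child. Total branch length
#' and the patristic distance matrix are conserved. Already-unrooted trees are
#' returned unchanged.
#'
#' @param tree A `phylo` tree with at least 3 leaves.
#' @return An unrooted `phylo` tree (base node of degree >= 3).
#' @export
unroot_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::Ntip(tree) < 3L) stop("cannot unroot a tree with fewer than 3 leaves")
  if (!is_rooted_tree(tree)) return(tree)
  ape::unroot(tree)
}

# ---- polytomy resolution -----------------------------------------------

# Recursive nested representation: a leaf is list(label=, length=);
# an internal node is list(children=list(...), length=, label=).
phylo_to_nested <- function(tree) {
  n_tip <- ape::Ntip(tree)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  build <- function(node, edge_idx) {
    len <- if (!is.null(tree$edge.length) && !is.na(edge_idx)) {
      tree$edge.length[edge_idx]
    } else NA_real_
    if (node <= n_tip) {
      return(list(label = tree$tip.label[node], length = len))
    }
    ks <- kids[[as.character(node)]]
    lab <- if (!is.null(tree$node.label)) tree$node.label[node - n_tip] else NULL
    list(
      children = lapply(ks, function(k) build(tree$edge[k, 2], k)),
      length = len,
      label = if (!is.null(lab) && !is.na(lab) && nzchar(lab)) lab else NULL
    )
  }
  build(n_tip + 1L, NA)
}

nested_to_newick <- function(node) {
  fmt_len <- function(len) {
    if (is.na(len)) "" else sprintf(":%.17g", len)
  }
  if (!is.null(node$label) && is.null(node$children)) {
    lab <- node$label
    if (grepl("[ ()\\[\\]:;,]", lab)) lab <- paste0("'", lab, "'")
    return(paste0(lab, fmt_len(node$length)))
  }
  inner <- paste(vapply(node$children, nested_to_newick, character(1)),
                 collapse = ",")
  lab <- if (!is.null(node$label)) node$label else ""
  paste0("(", inner, ")", lab, fmt_len(node$length))
}

#' Resolve polytomies into bifurcations
#'
#' Every internal node with more than two children is resolved
#' deterministically by grouping children left-to-right in their input order:
#' the first two children are joined under a new node, then that node is
#' joined with the third child, and so on (a ladder). Inserted edges carry
#' `inserted_length` (default 0), so with the default the patristic distance
#' matrix is unchanged. Already-bifurcating trees are returned unchanged.
#'
#' @param tree A `phylo` tree.
#' @param inserted_length Non-negative length assigned to inserted edges.
#' @return A strictly bifurcating `phylo` tree.
#' @export
resolve_polytomy <- function(tree, inserted_length = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (inserted_length < 0) stop("inserted_length must be non-negative")
  has_lengths <- !is.null(tree$edge.length)
  resolve <- function(node) {
    if (is.null(node$children)) return(node)
    node$children <- lapply(node$children, resolve)
    while (length(node$children) > 2L) {
      merged <- list(
        children = node$children[1:2],
        length = if (has_lengths) inserted_length else NA_real_,
        label = NULL
      )
      node$children <- c(list(merged), node$children[-(1:2)])
    }
    node
  }
  tab <- tabulate(tree$edge[, 1])
  if (all(tab[tab > 0] == 2L)) return(tree)
  nested <- resolve(phylo_to_nested(tree))
  out <- ape::read.tree(text = paste0(nested_to_newick(nested), ";"))
  # rebuild exact lengths lost to text formatting
  if (!has_lengths) out$edge.length <- NULL
  out
}
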