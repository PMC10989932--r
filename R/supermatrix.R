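#' Select codon positions from a nucleotide alignment
#'
#' Keeps the alignment columns whose codon position (1, 2 or 3, computed as
#' `((p - 1) mod 3) + 1`) lies in `keep`, preserving column order. The
#' alignment length must be divisible by 3.
#'
#' @param aln A nucleotide [aln_matrix()].
#' @param keep Subset of `c(1, 2, 3)`.
#' @return The column-filtered alignment.
#' @examples
#' a <- aln_matrix(c(x = "ATGAAA"))
#' split_codon_sites(a, c(1, 2))[["x"]]  # "ATAA"
#' @export
split_codon_sites <- function(aln, keep) {
  stopifnot(inherits(aln, "aln"))
  if (aln_alphabet(aln) != "nucleotide") {
    stop("codon-site selection requires nucleotide data")
  }
  keep <- sort(unique(as.integer(keep)))
  if (length(keep) == 0L || !all(keep %in% 1:3)) {
    stop("'keep' must be a non-empty subset of {1, 2, 3}")
  }
  t <- aln_ncol(aln)
  if (t %% 3L != 0L) {
    stop(sprintf("alignment length %d is not divisible by 3", t))
  }
  pos <- which(((seq_len(t) - 1L) %% 3L + 1L) %in% keep)
  out <- vapply(aln, function(s) {
    paste(strsplit(s, "", fixed = TRUE)[[1]][pos], collapse = "")
  }, character(1))
  aln_matrix(out, alphabet = aln_alphabet(aln))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' The taxon set of the supermatrix is the union of the taxa over all genes
#' (in order of first appearance). Each row is the per-gene blocks in the
#' order of the input map; a taxon missing from a gene gets a block of `?`
#' of that gene's width (gaps *within* present genes remain `-`). The
#' partition scheme records one contiguous 1-based inclusive charset per
#' gene.
#'
#' @param genes Named list of [aln_matrix()] objects (insertion order is the
#'   partition order).
#' @return A `concat_result`: `matrix` (the supermatrix), `scheme` (a
#'   `partition_scheme` data frame with `name`, `start`, `end`,
#'   `codon_stride`), and `occupancy` (per-taxon fraction of non-`?`
#'   columns).
#' @export
concatenate <- function(genes) {
  if (length(genes) == 0L) stop("no gene alignments supplied")
  if (is.null(names(genes)) || any(!nzchar(names(genes)))) {
    stop("gene alignments must be named")
  }
  alphabets <- unique(vapply(genes, aln_alphabet, character(1)))
  if (length(alphabets) != 1L) {
    stop("cannot concatenate nucleotide and amino-acid alignments")
  }
  taxa <- unique(unlist(lapply(genes, names), use.names = FALSE))
  widths <- vapply(genes, aln_ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(taxa, function(tx) {
    paste(vapply(genes, function(g) {
      if (tx %in% names(g)) g[[tx]] else strrep("?", aln_ncol(g))
    }, character(1)), collapse = "")
  }, character(1))
  mat <- aln_matrix(rows, labels = taxa, alphabet = alphabets)
  scheme <- new_partition_scheme(names(genes), starts, ends)
  qs <- vapply(mat, function(s) {
    nchar(s) - nchar(gsub("?", "", s, fixed = TRUE))
  }, integer(1))
  occupancy <- 1 - qs / aln_ncol(mat)
  structure(list(matrix = mat, scheme = scheme, occupancy = occupancy),
            class = "concat_result")
}

#' @export
print.concat_result <- function(x, ...) {
  cat(sprintf("<concat_result> %d taxa x %d sites, %d partition(s)\n",
              length(x$matrix), aln_ncol(x$matrix), nrow(x$scheme)))
  invisible(x)
}

new_partition_scheme <- function(name, start, end, codon_stride = NA_integer_) {
  df <- data.frame(name = as.character(name), start = as.integer(start),
                   end = as.integer(end),
                   codon_stride = as.integer(codon_stride),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty partition scheme")
  if (any(df$start > df$end)) stop("partition start exceeds end")
  if (df$start[1] != 1L ||
      (nrow(df) > 1L && any(df$start[-1] != df$end[-nrow(df)] + 1L))) {
    stop("partitions must be contiguous and cover 1..t")
  }
  class(df) <- c("partition_scheme", "data.frame")
  df
}

#' Slice a supermatrix back into one gene block
#'
#' @param concat A `concat_result`.
#' @param gene Partition name.
#' @return The gene's block of the supermatrix as an [aln_matrix()]
#'   (including `?`-filled rows for taxa missing that gene).
#' @export
slice_supermatrix <- function(concat, gene) {
  stopifnot(inherits(concat, "concat_result"))
  i <- match(gene, concat$scheme$name)
  if (is.na(i)) stop(sprintf("no partition named '%s'", gene))
  s <- concat$scheme$start[i]; e <- concat$scheme$end[i]
  out <- vapply(concat$matrix, substr, character(1), start = s, stop = e)
  aln_matrix(out, alphabet = aln_alphabet(concat$matrix))
}

#' Back-translate an aligned protein onto its source codons
#'
#' Maps every amino-acid column to three nucleotide columns: a residue is
#' replaced by its source codon (consumed left-to-right from the unaligned
#' CDS), `-` becomes `---`, and `?`/`X` become `???` (the codon is still
#' consumed for `X`). Each taxon's CDS must translate, under `code`, to its
#' aligned row with gaps removed; a terminal stop codon on the CDS is
#' tolerated and dropped.
#'
#' @param aa_aln Amino-acid [aln_matrix()].
#' @param cds Named character vector/list: taxon -> unaligned nucleotide CDS.
#' @param code The `genetic_code` used for verification.
#' @return A nucleotide alignment of width `3 * ncol(aa_aln)`.
#' @export
back_translate <- function(aa_aln, cds, code = genetic_code(1)) {
  stopifnot(inherits(aa_aln, "aln"))
  if (aln_alphabet(aa_aln) != "amino_acid") {
    stop("back_translate expects an amino-acid alignment")
  }
  out <- character(length(aa_aln))
  for (i in seq_along(aa_aln)) {
    tx <- names(aa_aln)[i]
    if (!tx %in% names(cds)) stop(sprintf("missing CDS for taxon '%s'", tx))
    nt <- toupper(gsub("U", "T", cds[[tx]], fixed = TRUE))
    aa_row <- strsplit(aa_aln[[i]], "", fixed = TRUE)[[1]]
    residues <- aa_row[!aa_row %in% c("-", "?")]
    n_res <- length(residues)
    # tolerate (and drop) one terminal stop codon on the CDS
    if (nchar(nt) == 3L * (n_res + 1L)) {
      last <- substr(nt, nchar(nt) - 2L, nchar(nt))
      if (translate_codons(last, code) == "*") {
        nt <- substr(nt, 1L, nchar(nt) - 3L)
      }
    }
    if (nchar(nt) != 3L * n_res) {
      stop(sprintf("taxon '%s': CDS length %d does not match %d residues",
                   tx, nchar(nt), n_res))
    }
    starts <- 3L * seq_len(n_res) - 2L
    codons <- substring(nt, starts, starts + 2L)
    trans <- translate_codons(codons, code)
    mismatch <- which(trans != residues & !(trans == "*" & residues == "X"))
    if (length(mismatch)) {
      stop(sprintf(
        "taxon '%s': translation mismatch at amino-acid position %d ('%s' vs aligned '%s')",
        tx, mismatch[1], trans[mismatch[1]], residues[mismatch[1]]
      ))
    }
    k <- 0L
    pieces <- vapply(aa_row, function(a) {
      if (a == "-") return("---")
      if (a == "?") return("???")
      k <<- k + 1L
      if (a == "X") return("???")
      codons[k]
    }, character(1), USE.NAMES = FALSE)
    out[i] <- paste(pieces, collapse = "")
  }
  aln_matrix(out, labels = names(aa_aln), alphabet = "nucleotide")
}

#' Replace frameshift marks with missing-data characters
#'
#' Codon-aware refinement tools mark detected frameshifts with `!` (and, in
#' their nucleotide output, `*`); these characters break downstream parsers.
#' Every `!` is replaced by `?`; `*` is replaced only in nucleotide data (in
#' amino-acid data `*` is a legitimate stop and is preserved). The character
#' count of every row is unchanged.
#'
#' @param aln An [aln_matrix()].
#' @return The sanitised alignment.
#' @export
sanitize_frameshift_marks <- function(aln) {
  stopifnot(inherits(aln, "aln"))
  out <- gsub("!", "?", unclass(aln), fixed = TRUE)
  if (aln_alphabet(aln) == "nucleotide") {
    out <- gsub("*", "?", out, fixed = TRUE)
  }
  aln_matrix(out, labels = names(aln), alphabet = aln_alphabet(aln))
}

#' Write a partition scheme
#'
#' Serialises a partition scheme as a NEXUS sets block (`charset name =
#' start-end;`) or RAxML-style lines (`DNA, name = start-end`). A codon
#' stride k is written with the `\\3` offset notation
#' (`(start + k - 1)-end\\3`). Coordinates are 1-based inclusive.
#'
#' @param scheme A `partition_scheme` data frame.
#' @param dialect `"nexus_sets"` or `"raxml"`.
#' @param path Optional output path.
#' @param datatype Data type keyword for RAxML lines (default `"DNA"`).
#' @return The serialised text.
#' @export
write_partition_scheme <- function(scheme, dialect = c("nexus_sets", "raxml"),
                                   path = NULL, datatype = "DNA") {
  dialect <- match.arg(dialect)
  if (!inherits(scheme, "partition_scheme") || nrow(scheme) == 0L) {
    stop("empty or invalid partition scheme")
  }
  range_txt <- function(i) {
    st <- scheme$start[i]; en <- scheme$end[i]; k <- scheme$codon_stride[i]
    if (is.na(k)) sprintf("%d-%d", st, en) else {
      sprintf("%d-%d\\3", st + k - 1L, en)
    }
  }
  ranges <- vapply(seq_len(nrow(scheme)), range_txt, character(1))
  txt <- switch(dialect,
    nexus_sets = paste0(
      "begin sets;\n",
      paste0("  charset ", scheme$name, " = ", ranges, ";", collapse = "\n"),
      "\nend;\n"
    ),
    raxml = paste0(
      paste0(datatype, ", ", scheme$name, " = ", ranges, collapse = "\n"),
      "\n"
    )
  )
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

#' Expand gene partitions into per-codon-position charsets
#'
#' Given a scheme of whole-gene partitions and the set of genes that are
#' protein-coding, returns a scheme where each coding gene contributes one
#' strided partition per codon position (`gene_pos1`, `gene_pos2`,
#' `gene_pos3`).
#'
#' @param scheme A `partition_scheme`.
#' @param pcg Character vector of partition names to expand.
#' @return A data frame in the same layout (not necessarily contiguous rows,
#'   since strided charsets interleave).
#' @export
codon_partition_scheme <- function(scheme, pcg) {
  stopifnot(inherits(scheme, "partition_scheme"))
  rows <- list()
  for (i in seq_len(nrow(scheme))) {
    if (scheme$name[i] %in% pcg) {
      for (k in 1:3) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s_pos%d", scheme$name[i], k),
          start = scheme$start[i], end = scheme$end[i],
          codon_stride = k, stringsAsFactors = FALSE
        )
      }
    } else {
      rows[[length(rows) + 1L]] <- scheme[i, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("partition_scheme", "data.frame")
  out
}
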