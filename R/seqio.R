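#' Construct an aligned sequence matrix
#'
#' The core alignment container: an ordered set of equal-length, uniquely
#' labelled sequence rows with a declared alphabet. Sequences are uppercased
#' on construction and, for nucleotide data, `U` is normalised to `T`.
#' Permitted characters are the IUPAC alphabet of the declared type plus
#' `-`, `?` and (pre-sanitisation) `!` and `*`.
#'
#' @param seqs Named character vector of sequences (or unnamed, with
#'   `labels` supplied separately).
#' @param labels Taxon labels; defaults to `names(seqs)`.
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `NULL` to auto-detect
#'   (>= 90\% of non-gap characters in `A,C,G,T,U,N` implies nucleotide).
#' @return An object of class `aln`: a named character vector with an
#'   `alphabet` attribute.
#' @export
aln_matrix <- function(seqs, labels = names(seqs), alphabet = NULL) {
  force(labels)
  seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("empty alignment")
  if (is.null(labels)) stop("taxon labels are required")
  labels <- as.character(labels)
  if (length(labels) != length(seqs)) stop("labels and sequences differ in length")
  if (any(!nzchar(labels))) stop("empty taxon label")
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop(sprintf("duplicate labels: %s", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- labels[lens != lens[1]][1]
    stop(sprintf("sequences not aligned: row '%s' has %d sites, expected %d",
                 bad, nchar(seqs[labels == bad]), lens[1]))
  }
  if (lens[1] == 0L) stop("alignment has zero columns")
  if (is.null(alphabet)) alphabet <- detect_alphabet(seqs)
  alphabet <- match.arg(alphabet, c("nucleotide", "amino_acid"))
  if (alphabet == "nucleotide" && any(grepl("U", seqs, fixed = TRUE))) {
    message("normalising 'U' to 'T' in nucleotide data")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  allowed <- if (alphabet == "nucleotide") {
    "ACGTURYSWKMBDHVN-?!*"
  } else {
    "ACDEFGHIKLMNPQRSTVWYBZJXUO-?!*"
  }
  bad_chr <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                     strsplit(allowed, "")[[1]])
  if (length(bad_chr)) {
    stop(sprintf("invalid %s character(s): %s", alphabet,
                 paste(bad_chr, collapse = " ")))
  }
  names(seqs) <- labels
  structure(seqs, alphabet = alphabet, class = "aln")
}

detect_alphabet <- function(seqs) {
  chars <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  chars <- chars[!chars %in% c("-", "?", "!", "*")]
  if (length(chars) == 0L) return("nucleotide")
  frac <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.9) "nucleotide" else "amino_acid"
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<aln> %d taxa x %d sites (%s)\n",
              length(x), aln_ncol(x), aln_alphabet(x)))
  show <- utils::head(seq_along(x), 6L)
  for (i in show) {
    s <- x[[i]]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-30s %s\n", names(x)[i], s))
  }
  if (length(x) > 6L) cat(sprintf("  ... %d more rows\n", length(x) - 6L))
  invisible(x)
}

#' @rdname aln_matrix
#' @param x An `aln` object.
#' @export
aln_ncol <- function(x) nchar(x[[1]])

#' @rdname aln_matrix
#' @export
aln_alphabet <- function(x) attr(x, "alphabet")

#' Read a multiple sequence alignment
#'
#' Supports FASTA, relaxed sequential PHYLIP (labels run up to the first
#' whitespace, so `organism_accession`-style labels survive) and the NEXUS
#' data block. All rows must have equal length.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param alphabet Optional override of the auto-detected alphabet.
#' @return An [aln_matrix()] object.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  seqs <- switch(format,
    fasta = {
      set <- Biostrings::readBStringSet(path)
      stats::setNames(as.character(set), names(set))
    },
    phylip = read_phylip_relaxed(path),
    nexus = {
      lst <- ape::read.nexus.data(path)
      vapply(lst, paste, character(1), collapse = "")
    }
  )
  if (length(seqs) == 0L) stop(sprintf("no sequences found in %s", path))
  # FASTA headers: keep text up to first whitespace as the label
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  aln_matrix(seqs, alphabet = alphabet)
}

read_phylip_relaxed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a PHYLIP file: missing header or rows")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("not a PHYLIP file: header must be 'ntax nchar'")
  }
  ntax <- as.integer(hdr[1]); nchar_decl <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) < ntax) stop("PHYLIP file has fewer rows than declared")
  labels <- character(ntax); seqs <- character(ntax)
  for (i in seq_len(ntax)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    labels[i] <- parts[1]
    seqs[i] <- paste(parts[-1], collapse = "")
  }
  # sequential continuation lines (sequences wrapped over extra lines)
  extra <- body[-seq_len(ntax)]
  if (length(extra) && nchar(seqs[1]) < nchar_decl) {
    per_tax <- length(extra) %/% ntax
    for (i in seq_len(ntax)) {
      block <- extra[seq.int(from = (i - 1L) * per_tax + 1L, length.out = per_tax)]
      seqs[i] <- paste0(seqs[i], gsub("\\s+", "", paste(block, collapse = "")))
    }
  }
  if (any(nchar(seqs) != nchar_decl)) {
    bad <- labels[nchar(seqs) != nchar_decl][1]
    stop(sprintf("sequences not aligned: row '%s' does not match declared length %d",
                 bad, nchar_decl))
  }
  stats::setNames(seqs, labels)
}

#' Write an alignment to FASTA, PHYLIP or NEXUS
#'
#' FASTA wraps sequences at 60 characters; PHYLIP is relaxed sequential with
#' an `ntax nchar` header; NEXUS emits a data block with `datatype=DNA` or
#' `protein`, `missing=?`, `gap=-`. Every format round-trips through
#' [read_alignment()] to an identical matrix.
#'
#' @param matrix An [aln_matrix()] object.
#' @param format `"fasta"`, `"phylip"` or `"nexus"`.
#' @param path Optional output file path.
#' @return The serialised text (one string), invisibly when `path` is given.
#' @export
write_alignment <- function(matrix, format = c("fasta", "phylip", "nexus"),
                            path = NULL) {
  stopifnot(inherits(matrix, "aln"))
  format <- match.arg(format)
  labs <- names(matrix)
  txt <- switch(format,
    fasta = {
      chunks <- vapply(seq_along(matrix), function(i) {
        s <- matrix[[i]]
        wrapped <- substring(s, seq(1, nchar(s), 60),
                             pmin(seq(1, nchar(s), 60) + 59, nchar(s)))
        paste0(">", labs[i], "\n", paste(wrapped, collapse = "\n"))
      }, character(1))
      paste0(paste(chunks, collapse = "\n"), "\n")
    },
    phylip = {
      paste0(length(matrix), " ", aln_ncol(matrix), "\n",
             paste0(labs, "  ", unname(matrix), collapse = "\n"), "\n")
    },
    nexus = {
      datatype <- if (aln_alphabet(matrix) == "nucleotide") "DNA" else "protein"
      paste0(
        "#NEXUS\n",
        "begin data;\n",
        sprintf("  dimensions ntax=%d nchar=%d;\n", length(matrix), aln_ncol(matrix)),
        sprintf("  format datatype=%s missing=? gap=-;\n", datatype),
        "  matrix\n",
        paste0("    ", labs, "  ", unname(matrix), collapse = "\n"),
        "\n  ;\nend;\n"
      )
    }
  )
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}
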