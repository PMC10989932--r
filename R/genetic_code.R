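#' NCBI genetic-code tables
#'
#' Returns a genetic-code object for one of the bundled NCBI translation
#' tables: 1 (standard), 2 (vertebrate mitochondrial), 3 (yeast
#' mitochondrial), 4 (mold/protozoan mitochondrial), 5 (invertebrate
#' mitochondrial), 9 (echinoderm and flatworm mitochondrial), 11
#' (bacterial/plastid), 13 (ascidian mitochondrial), and 14 (alternative
#' flatworm mitochondrial). Table 9 is the one appropriate for flatworm
#' mitogenomes (AAA -> Asn, AGA -> Ser, TGA -> Trp).
#'
#' @param id NCBI translation-table id (integer).
#' @return An object of class `genetic_code` with elements `id`, `name`,
#'   `codons` (named character vector of 64 amino acids, stops as `*`) and
#'   `stops` (the stop codons).
#' @examples
#' code9 <- genetic_code(9)
#' code9$codons[["TGA"]]  # "W"
#' @export
genetic_code <- function(id = 1) {
  id <- as.integer(id)
  if (!id %in% bundled_code_ids()) {
    stop(sprintf("genetic code table %d is not bundled (available: %s)",
                 id, paste(bundled_code_ids(), collapse = ", ")))
  }
  codons <- Biostrings::getGeneticCode(as.character(id))
  attr(codons, "alt_init_codons") <- NULL
  tbl <- Biostrings::GENETIC_CODE_TABLE
  nm <- tbl$name[match(as.character(id), tbl$id)]
  structure(
    list(id = id, name = nm, codons = codons,
         stops = names(codons)[codons == "*"]),
    class = "genetic_code"
  )
}

#' @rdname genetic_code
#' @export
bundled_code_ids <- function() c(1L, 2L, 3L, 4L, 5L, 9L, 11L, 13L, 14L)

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> NCBI table %d (%s); stops: %s\n",
              x$id, x$name, paste(x$stops, collapse = ", ")))
  invisible(x)
}

# IUPAC nucleotide expansions used for ambiguity-aware translation
iupac_nt_expansion <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

#' Translate a coding sequence
#'
#' Translates a gap-free nucleotide sequence codon-by-codon under an NCBI
#' genetic code. An incomplete final codon is dropped with a warning. Stop
#' codons render as `*`; internal stops trigger a warning. Codons containing
#' IUPAC ambiguity codes translate normally when every expansion agrees on
#' the amino acid (synonymous ambiguity), otherwise they yield `X`.
#'
#' @param seq A single nucleotide string (no gaps).
#' @param code A `genetic_code` object (default: table 1).
#' @param strip_terminal_stop Drop a final `*` from the translation?
#' @return The amino-acid string.
#' @examples
#' translate_cds("ATGAAATAA", genetic_code(9), strip_terminal_stop = TRUE) # "MN"
#' @export
translate_cds <- function(seq, code = genetic_code(1),
                          strip_terminal_stop = FALSE) {
  stopifnot(inherits(code, "genetic_code"))
  if (length(seq) != 1L || !nzchar(seq)) stop("empty sequence")
  seq <- toupper(gsub("U", "T", seq, fixed = TRUE))
  if (grepl("[-?]", seq)) stop("translate_cds requires a gap-free sequence")
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than one codon")
  n_codon <- n %/% 3L
  if (n %% 3L != 0L) {
    warning(sprintf("incomplete final codon (%d trailing base(s)) dropped",
                    n %% 3L))
  }
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(seq, starts, starts + 2L)
  aa <- translate_codons(codons, code)
  if (strip_terminal_stop && aa[n_codon] == "*") aa <- aa[-n_codon]
  internal_stops <- which(aa == "*")
  internal_stops <- internal_stops[internal_stops < length(aa)]
  if (length(internal_stops)) {
    warning(sprintf("internal stop codon(s) at amino-acid position(s) %s",
                    paste(internal_stops, collapse = ", ")))
  }
  paste(aa, collapse = "")
}

translate_codons <- function(codons, code) {
  map <- code$codons
  aa <- unname(map[codons])
  unresolved <- which(is.na(aa))
  if (length(unresolved)) {
    exp <- iupac_nt_expansion()
    for (i in unresolved) {
      bases <- strsplit(codons[i], "", fixed = TRUE)[[1]]
      sets <- exp[bases]
      if (length(sets) != 3L || any(vapply(sets, is.null, logical(1)))) {
        aa[i] <- "X"
        next
      }
      combos <- expand.grid(sets, stringsAsFactors = FALSE)
      cands <- unique(map[paste0(combos[[1]], combos[[2]], combos[[3]])])
      aa[i] <- if (length(cands) == 1L && !is.na(cands)) cands else "X"
    }
  }
  aa
}

#' Reverse-complement a nucleotide string
#'
#' IUPAC ambiguity codes are complemented correctly (via Biostrings).
#'
#' @param seq A single nucleotide string.
#' @return The reverse complement, as a plain string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
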