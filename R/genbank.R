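#' Read a GenBank flat file
#'
#' Parses one or more GenBank records (LOCUS ... //) from a flat file:
#' accession, organism, lineage, the FEATURES table (feature kind, location
#' with `join()`/`complement()` handled structurally, `/gene`, `/product`
#' and `/transl_table` qualifiers) and the ORIGIN sequence. Feature
#' coordinates are validated against the sequence length.
#'
#' @param path Path to a GenBank flat file (`.gb`).
#' @return A list of `genbank_record` objects, each with elements
#'   `accession`, `organism`, `lineage`, `features` and `sequence`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) stop("no GenBank records found (missing '//')")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  records <- vector("list", length(ends))
  for (r in seq_along(ends)) {
    block <- lines[starts[r]:ends[r]]
    records[[r]] <- parse_genbank_record(block)
  }
  records
}

parse_genbank_record <- function(lines) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("malformed record: no LOCUS line")
  locus_name <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i[1]])), "\\s+")[[1]][1]

  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i)) {
    strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "\\s+")[[1]][1]
  } else locus_name
  if (is.na(accession) || !nzchar(accession)) accession <- locus_name

  org_i <- grep("^\\s{2}ORGANISM", lines)
  organism <- ""
  lineage <- character(0)
  if (length(org_i)) {
    organism <- trimws(sub("^\\s{2}ORGANISM", "", lines[org_i[1]]))
    j <- org_i[1] + 1L
    lin_lines <- character(0)
    while (j <= length(lines) && grepl("^\\s{4,}\\S", lines[j]) &&
           !grepl("^FEATURES|^REFERENCE|^COMMENT", lines[j])) {
      lin_lines <- c(lin_lines, trimws(lines[j]))
      j <- j + 1L
    }
    lin <- paste(lin_lines, collapse = " ")
    lin <- sub("\\.$", "", lin)
    lineage <- trimws(strsplit(lin, ";")[[1]])
    lineage <- lineage[nzchar(lineage)]
  }

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0L) {
    stop(sprintf("record %s: missing ORIGIN block", accession))
  }
  seq_lines <- lines[(origin_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop(sprintf("record %s: empty ORIGIN block", accession))

  features <- list()
  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i)) {
    feat_lines <- lines[(feat_i[1] + 1L):(origin_i[1] - 1L)]
    features <- parse_feature_table(feat_lines, accession, nchar(sequence))
  }

  structure(
    list(accession = accession, organism = organism, lineage = lineage,
         features = features, sequence = sequence),
    class = "genbank_record"
  )
}

#' @export
print.genbank_record <- function(x, ...) {
  cat(sprintf("<genbank_record> %s (%s), %d bp, %d feature(s)\n",
              x$accession, x$organism, nchar(x$sequence), length(x$features)))
  invisible(x)
}

parse_feature_table <- function(lines, accession, seq_len) {
  # a feature header starts at column 6; qualifiers/continuations are deeper
  hdr_idx <- grep("^\\s{5}\\S", lines)
  features <- list()
  for (h in seq_along(hdr_idx)) {
    i <- hdr_idx[h]
    end <- if (h < length(hdr_idx)) hdr_idx[h + 1L] - 1L else length(lines)
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- parts[1]
    if (key == "source") next
    rest <- lines[seq.int(i, end)]
    rest[1] <- sub("^\\s{5}\\S+\\s*", "", rest[1])
    rest <- trimws(rest)
    # location text = leading lines up to the first qualifier
    qual_start <- grep("^/", rest)
    loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(rest)
    loc_txt <- paste(rest[seq_len(loc_end)], collapse = "")
    quals <- parse_qualifiers(rest[seq.int(loc_end + 1L, length.out = length(rest) - loc_end)])
    loc <- parse_location(loc_txt)
    if (any(loc$intervals > seq_len) || any(loc$intervals < 1L)) {
      stop(sprintf("record %s: feature %s coordinate outside sequence [1, %d]",
                   accession, key, seq_len))
    }
    kind <- if (key %in% c("CDS", "tRNA", "rRNA")) key else "other"
    features[[length(features) + 1L]] <- list(
      kind = kind,
      key = key,
      name = quals$gene %||% quals$product %||% NA_character_,
      gene = quals$gene,
      product = quals$product,
      intervals = loc$intervals,
      strand = loc$strand,
      transl_table = if (!is.null(quals$transl_table)) {
        as.integer(quals$transl_table)
      } else NULL
    )
  }
  features
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  # re-join continuation lines onto their /qualifier line
  joined <- character(0)
  for (ln in lines) {
    if (grepl("^/", ln) || length(joined) == 0L) {
      joined <- c(joined, ln)
    } else {
      joined[length(joined)] <- paste(joined[length(joined)], ln)
    }
  }
  out <- list()
  for (ln in joined) {
    m <- regmatches(ln, regexec("^/([A-Za-z_]+)(=(.*))?$", ln))[[1]]
    if (length(m) == 0L) next
    key <- m[2]
    val <- if (nchar(m[4])) gsub('^"|"$', "", m[4]) else TRUE
    out[[key]] <- val
  }
  out
}

parse_location <- function(txt) {
  txt <- gsub("\\s", "", txt)
  strand <- if (grepl("complement", txt)) "-" else "+"
  txt <- gsub("complement\\(|join\\(|order\\(|\\)", "", txt)
  txt <- gsub("[<>]", "", txt)
  pieces <- strsplit(txt, ",")[[1]]
  ivs <- t(vapply(pieces, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums) || nums[2] < nums[1]) {
      stop(sprintf("malformed feature location: '%s'", p))
    }
    nums
  }, integer(2)))
  dimnames(ivs) <- NULL
  list(intervals = ivs, strand = strand)
}

#' Remove redundant GenBank records
#'
#' Records are grouped by identical genome sequence (case-insensitive full
#' string). Within each group one record is kept: an accession starting
#' `NC_` (RefSeq) is retained preferentially; otherwise the first record
#' encountered is kept. The order of kept records follows the input order.
#'
#' @param records List of `genbank_record` objects.
#' @return A list with elements `kept` and `removed` (a partition of the
#'   input).
#' @export
deduplicate_records <- function(records) {
  if (length(records) == 0L) return(list(kept = list(), removed = list()))
  keys <- vapply(records, function(r) toupper(r$sequence), character(1))
  groups <- split(seq_along(records), factor(keys, levels = unique(keys)))
  keep_idx <- vapply(groups, function(idx) {
    accs <- vapply(records[idx], function(r) r$accession, character(1))
    nc <- idx[startsWith(accs, "NC_")]
    if (length(nc)) nc[1] else idx[1]
  }, integer(1))
  keep_idx <- sort(keep_idx)
  list(kept = records[keep_idx],
       removed = records[setdiff(seq_along(records), keep_idx)])
}

# ---- gene-name unification ---------------------------------------------

normalize_gene_key <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Gene-name alias maps
#'
#' `read_name_map()` reads a 2-column TSV of (Old Name, New Name) rows, with
#' or without a header line. `default_name_map()` returns the bundled map of
#' common mitochondrial gene aliases (cox1-cox3, cob, nad1-nad6, nad4L,
#' atp6, atp8, rrnL, rrnS and the tRNAs); it is a curated, user-replaceable
#' superset. Lookup is case-insensitive on a normalised key (lowercase,
#' punctuation and whitespace stripped).
#'
#' @param path Path to a 2-column TSV file.
#' @return A `name_map` object (data frame with columns `old`, `new` plus a
#'   normalised lookup key).
#' @export
read_name_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("old", "new"))
  if (nrow(df) && normalize_gene_key(df$old[1]) %in%
        c("oldname", "rawname")) {
    df <- df[-1, , drop = FALSE]
  }
  new_name_map(df$old, df$new)
}

new_name_map <- function(old, new) {
  df <- data.frame(old = as.character(old), new = as.character(new),
                   stringsAsFactors = FALSE)
  df$key <- normalize_gene_key(df$old)
  dup <- df$key[duplicated(df$key)]
  if (length(dup)) {
    stop(sprintf("duplicate old names after normalisation: %s",
                 paste(unique(dup), collapse = ", ")))
  }
  structure(df, class = c("name_map", "data.frame"))
}

#' @rdname read_name_map
#' @export
default_name_map <- function() {
  path <- system.file("extdata", "gene_aliases.tsv", package = "phylokit",
                      mustWork = TRUE)
  read_name_map(path)
}

#' Unify a raw gene name against an alias map
#'
#' @param raw Raw gene name (from a `/gene` or `/product` qualifier).
#' @param map A `name_map` (default: the bundled mitochondrial map).
#' @return A list with `canonical` (the mapped name, or the normalised raw
#'   name when unmatched) and `matched` (logical).
#' @examples
#' unify_gene_name("COI")$canonical  # "cox1"
#' @export
unify_gene_name <- function(raw, map = default_name_map()) {
  if (!nzchar(raw)) stop("empty gene name")
  key <- normalize_gene_key(raw)
  hit <- match(key, map$key)
  if (is.na(hit)) {
    list(canonical = key, matched = FALSE)
  } else {
    list(canonical = map$new[hit], matched = TRUE)
  }
}

#' Build a taxon label from a record
#'
#' The template may use the placeholders `{organism}` (spaces replaced by
#' `_`) and `{accession}`. Default: `"{organism}_{accession}"`.
#'
#' @param record A `genbank_record`.
#' @param template Label template string.
#' @return The taxon label.
#' @export
make_taxon_label <- function(record, template = "{organism}_{accession}") {
  placeholders <- regmatches(template, gregexpr("\\{[^}]*\\}", template))[[1]]
  unknown <- setdiff(placeholders, c("{organism}", "{accession}"))
  if (length(unknown)) {
    stop(sprintf("unknown placeholder: %s", paste(unknown, collapse = ", ")))
  }
  out <- gsub("{organism}", gsub(" ", "_", record$organism), template,
              fixed = TRUE)
  gsub("{accession}", record$accession, out, fixed = TRUE)
}

#' Extract genes from GenBank records
#'
#' For every feature of a selected kind, the feature's intervals are cut from
#' the genome in order, concatenated, and reverse-complemented for
#' minus-strand features. Gene names are unified through the alias map
#' (lookup order: `/gene`, then `/product`); unmatched names pass through
#' normalised and are tallied in the unmatched report. CDS features are
#' additionally translated, using the feature's `/transl_table` when present,
#' else `code`, with the terminal stop stripped.
#'
#' @param records List of `genbank_record` objects (deduplicate first).
#' @param map A `name_map` for alias unification.
#' @param code Fallback `genetic_code` for CDS translation.
#' @param kinds Feature kinds to extract.
#' @param label_template Passed to [make_taxon_label()].
#' @return An `extraction_bundle`: `genes` (per canonical gene, a list with
#'   `nt` and, for CDS, `aa` named sequence vectors), and `unmatched`
#'   (data frame `raw_name`, `suggested_name`, `count`).
#' @export
extract_genes <- function(records, map = default_name_map(),
                          code = genetic_code(1),
                          kinds = c("CDS", "tRNA", "rRNA"),
                          label_template = "{organism}_{accession}") {
  stopifnot(inherits(code, "genetic_code"))
  genes <- list()
  unmatched <- list()
  for (rec in records) {
    label <- make_taxon_label(rec, label_template)
    for (ft in rec$features) {
      if (!ft$kind %in% kinds) next
      raw <- ft$name
      if (is.null(raw) || is.na(raw)) next
      uni <- unify_gene_name(raw, map)
      if (!uni$matched) {
        k <- raw
        if (is.null(unmatched[[k]])) {
          unmatched[[k]] <- list(suggested = uni$canonical, count = 0L)
        }
        unmatched[[k]]$count <- unmatched[[k]]$count + 1L
      }
      gene <- uni$canonical
      nt <- feature_sequence(rec, ft)
      if (is.null(genes[[gene]])) {
        genes[[gene]] <- list(nt = character(0), aa = character(0),
                              kind = ft$kind)
      }
      lab <- label
      if (lab %in% names(genes[[gene]]$nt)) {
        n_prev <- sum(startsWith(names(genes[[gene]]$nt), lab))
        lab <- sprintf("%s_%d", lab, n_prev + 1L)
        message(sprintf("duplicate (gene, taxon) pair %s/%s renamed to %s",
                        gene, label, lab))
      }
      genes[[gene]]$nt[[lab]] <- nt
      if (ft$kind == "CDS") {
        ft_code <- if (!is.null(ft$transl_table)) {
          genetic_code(ft$transl_table)
        } else code
        genes[[gene]]$aa[[lab]] <- suppressWarnings(
          translate_cds(nt, ft_code, strip_terminal_stop = TRUE)
        )
      }
    }
  }
  unmatched_df <- if (length(unmatched)) {
    data.frame(
      raw_name = names(unmatched),
      suggested_name = vapply(unmatched, function(u) u$suggested, character(1)),
      count = vapply(unmatched, function(u) u$count, integer(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(raw_name = character(0), suggested_name = character(0),
               count = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, unmatched = unmatched_df, code = code),
            class = "extraction_bundle")
}

feature_sequence <- function(record, ft) {
  parts <- apply(ft$intervals, 1, function(iv) {
    substr(record$sequence, iv[1], iv[2])
  })
  nt <- paste(parts, collapse = "")
  if (ft$strand == "-") nt <- reverse_complement(nt)
  nt
}

#' @export
print.extraction_bundle <- function(x, ...) {
  cat(sprintf("<extraction_bundle> %d gene(s): %s\n", length(x$genes),
              paste(names(x$genes), collapse = ", ")))
  if (nrow(x$unmatched)) {
    cat(sprintf("  %d unmatched raw name(s)\n", nrow(x$unmatched)))
  }
  invisible(x)
}

#' Write an extraction bundle to per-gene FASTA files
#'
#' Writes `<gene>.fasta` (nucleotide) and `<gene>.aa.fasta` (amino acid, CDS
#' only) for every gene, plus `name_for_unification.tsv` listing unmatched
#' raw names with suggested canonical names and counts.
#'
#' @param bundle An `extraction_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_extraction <- function(bundle, dir) {
  stopifnot(inherits(bundle, "extraction_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (gene in names(bundle$genes)) {
    g <- bundle$genes[[gene]]
    p <- file.path(dir, paste0(gene, ".fasta"))
    write_fasta_raw(g$nt, p)
    paths <- c(paths, p)
    if (length(g$aa)) {
      p <- file.path(dir, paste0(gene, ".aa.fasta"))
      write_fasta_raw(g$aa, p)
      paths <- c(paths, p)
    }
  }
  report <- file.path(dir, "name_for_unification.tsv")
  utils::write.table(bundle$unmatched, report, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("raw_name", "suggested_name", "count"))
  invisible(c(paths, report))
}

# unaligned FASTA writer (rows may have unequal lengths)
write_fasta_raw <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    wrapped <- substring(s, seq(1, nchar(s), 60),
                         pmin(seq(1, nchar(s), 60) + 59, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), wrapped), con)
  }
  invisible(path)
}
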