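#' Pair tree and alignment inputs for batch analyses
#'
#' When every tree name has a same-named alignment, trees and alignments are
#' combined by name; otherwise every tree is permuted with every alignment
#' (full Cartesian product). Tree-only analyses ignore alignments and
#' alignment-only analyses ignore trees.
#'
#' @param trees A `tree_collection` (or named list of trees); may be `NULL`
#'   for alignment-only analyses.
#' @param alns Named list of alignments (or their sources); may be `NULL`
#'   for tree-only analyses.
#' @param need `"both"`, `"tree"` or `"alignment"` - what the analysis
#'   requires.
#' @return A data frame with columns `tree` and `alignment` (either may be
#'   `NA` when unused), one row per job.
#' @export
pair_inputs <- function(trees = NULL, alns = NULL,
                        need = c("both", "tree", "alignment")) {
  need <- match.arg(need)
  tn <- names(trees)
  an <- names(alns)
  if (need == "tree") {
    if (length(tn) == 0L) stop("analysis requires tree input")
    return(data.frame(tree = tn, alignment = NA_character_,
                      stringsAsFactors = FALSE))
  }
  if (need == "alignment") {
    if (length(an) == 0L) stop("analysis requires alignment input")
    return(data.frame(tree = NA_character_, alignment = an,
                      stringsAsFactors = FALSE))
  }
  if (length(tn) == 0L || length(an) == 0L) {
    stop("analysis requires both tree and alignment inputs")
  }
  if (all(tn %in% an)) {
    data.frame(tree = tn, alignment = tn, stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(alignment = an, tree = tn,
                        stringsAsFactors = FALSE)[, c("tree", "alignment")]
    rownames(grid) <- NULL
    grid
  }
}

#' Write an iTOL simple-bar dataset
#'
#' Emits a plain-text dataset in the iTOL `DATASET_SIMPLEBAR` grammar:
#' header lines (dataset type, separator, label, colour), a `DATA` line,
#' then one `taxon,value` line per taxon. The file can be dragged onto an
#' iTOL tree to draw per-taxon bars (e.g. long-branch scores or root-to-tip
#' lengths).
#'
#' @param values Non-empty named numeric vector (taxon -> finite value).
#' @param title Dataset label.
#' @param path Optional output path.
#' @param color Bar colour (hex).
#' @return The dataset text.
#' @export
write_itol_simplebar <- function(values, title, path = NULL,
                                 color = "#4575b4") {
  if (length(values) == 0L) stop("no values to write")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by taxon")
  }
  if (any(!is.finite(values))) stop("non-finite value in iTOL dataset")
  txt <- paste0(
    "DATASET_SIMPLEBAR\n",
    "SEPARATOR COMMA\n",
    sprintf("DATASET_LABEL,%s\n", title),
    sprintf("COLOR,%s\n", color),
    "DATA\n",
    paste0(names(values), ",", fmt_num(values), collapse = "\n"),
    "\n"
  )
  if (!is.null(path)) {
    cat(txt, file = path)
    return(invisible(txt))
  }
  txt
}

# fixed-notation significant-digit formatter: byte-stable across runs
fmt_num <- function(x, digits = 6L) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.*g", digits, v)
  }, character(1))
}

write_csv_report <- function(df, path, digits = 6L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run tree-based analyses over paired inputs
#'
#' Batch driver mirroring the analysis menu: reads the tree and alignment
#' files, pairs them by stem (same-name match, else Cartesian product), runs
#' the selected analysis for every job and writes the result CSVs (and iTOL
#' bar datasets where meaningful) into `outdir`. Outputs are deterministic:
#' identical inputs produce byte-identical files.
#'
#' @param analysis One of `"saturation"`, `"lb"`, `"spurious"`,
#'   `"treeness"`, `"rcv"`, `"s2n"`, `"patristic"`, `"root2tip"`,
#'   `"evorate"`, `"unroot"`, `"polytomy"`.
#' @param tree_files Character vector of Newick/NEXUS tree files.
#' @param aln_files Character vector of alignment files.
#' @param outdir Output directory (created).
#' @param outgroup Optional outgroup labels (applied to every tree before
#'   tree statistics; required for `root2tip` on unrooted trees).
#' @param threshold Spurious-species threshold (default 20).
#' @param fit Saturation regression mode.
#' @param tree_format,aln_format Input formats.
#' @param digits Significant digits in numeric output.
#' @return Invisibly, the paths of all files written.
#' @export
run_treestats <- function(analysis, tree_files = character(0),
                          aln_files = character(0), outdir,
                          outgroup = NULL, threshold = 20,
                          fit = "ols_intercept",
                          tree_format = "newick", aln_format = "fasta",
                          digits = 6L) {
  analyses <- c("saturation", "lb", "spurious", "treeness", "rcv", "s2n",
                "patristic", "root2tip", "evorate", "unroot", "polytomy")
  if (!analysis %in% analyses) {
    stop(sprintf("unknown analysis '%s' (expected one of: %s)",
                 analysis, paste(analyses, collapse = ", ")))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  need <- switch(analysis,
                 saturation = , s2n = "both",
                 rcv = "alignment",
                 "tree")
  trees <- list()
  for (f in tree_files) trees <- c(trees, read_tree_file(f, tree_format))
  alns <- list()
  for (f in aln_files) {
    alns[[tools::file_path_sans_ext(basename(f))]] <-
      read_alignment(f, aln_format)
  }
  jobs <- pair_inputs(if (length(trees)) trees else NULL,
                      if (length(alns)) alns else NULL, need = need)
  written <- character(0)
  for (j in seq_len(nrow(jobs))) {
    tr <- if (!is.na(jobs$tree[j])) trees[[jobs$tree[j]]] else NULL
    if (!is.null(tr) && !is.null(outgroup) && length(outgroup)) {
      tr <- set_outgroup(tr, outgroup)
    }
    al <- if (!is.na(jobs$alignment[j])) alns[[jobs$alignment[j]]] else NULL
    stem <- paste(stats::na.omit(unlist(jobs[j, ])), collapse = "__")
    out <- run_one_treestat(analysis, tr, al, outdir, stem, threshold, fit,
                            digits)
    written <- c(written, out)
  }
  message(sprintf("wrote %d file(s) to %s:\n%s", length(written), outdir,
                  paste(" -", basename(written), collapse = "\n")))
  invisible(written)
}

run_one_treestat <- function(analysis, tree, aln, outdir, stem, threshold,
                             fit, digits) {
  p <- function(name) file.path(outdir, sprintf("%s.%s", stem, name))
  written <- character(0)
  add <- function(path) written <<- c(written, path)
  switch(analysis,
    lb = {
      rep <- lb_scores(tree)
      df <- data.frame(taxon = rep$scores$taxon,
                       mean_patristic = rep$scores$mean_pd,
                       lb_score = rep$scores$lb)
      add(write_csv_report(df, p("Long branch scores.csv"), digits))
      overall <- data.frame(statistic = c("mean_pd_all", names(rep$summary)),
                            value = c(rep$mean_pd_all, unname(rep$summary)))
      add(write_csv_report(overall, p("Long branch scores overall.csv"),
                           digits))
      itol <- stats::setNames(rep$scores$lb, rep$scores$taxon)
      add_itol <- p("Long branch scores.itol.txt")
      write_itol_simplebar(itol, "Long branch score", add_itol)
      add(add_itol)
    },
    spurious = {
      sp <- spurious_species(tree, threshold)
      df <- data.frame(taxon = names(sp$terminal_lengths),
                       terminal_length = unname(sp$terminal_lengths),
                       median_length = sp$median_length,
                       flagged = names(sp$terminal_lengths) %in% sp$flagged)
      add(write_csv_report(df, p("Spurious species.csv"), digits))
    },
    treeness = {
      add(write_csv_report(data.frame(tree = stem, treeness = treeness(tree)),
                           p("treeness.csv"), digits))
    },
    rcv = {
      r <- rcv(aln)
      add(write_csv_report(data.frame(alignment = stem, RCV = r$rcv),
                           p("RCV.csv"), digits))
      df <- data.frame(taxon = names(r$per_taxon),
                       RCV = unname(r$per_taxon))
      add(write_csv_report(df, p("Species.RCV.csv"), digits))
    },
    s2n = {
      s <- signal_to_noise(tree, aln)
      df <- data.frame(job = stem, signal_to_noise = s$signal_to_noise,
                       treeness = s$treeness, RCV = s$rcv)
      add(write_csv_report(df, p("signal-to-noise.csv"), digits))
    },
    saturation = {
      sat <- saturation_regression(tree, aln, fit)
      df <- sat$pairs
      names(df) <- c("taxon1", "taxon2", "patristic_distance",
                     "pairwise_difference", "pairwise_identity",
                     "compared_sites")
      add(write_csv_report(df, p("saturation.csv"), digits))
      reg <- data.frame(slope = sat$slope, intercept = sat$intercept,
                        r_squared = sat$r2, fit = sat$fit,
                        n_pairs = sat$n_pairs)
      add(write_csv_report(reg, p("saturation.regression.csv"), digits))
      plot_df <- data.frame(x_patristic = fmt_num(df$patristic_distance, digits),
                            y_difference = fmt_num(df$pairwise_difference, digits))
      tsv <- p("plot_data.tsv")
      utils::write.table(plot_df, tsv, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add(tsv)
    },
    patristic = {
      d <- patristic_matrix(tree)
      pairs <- which(upper.tri(d), arr.ind = TRUE)
      df <- data.frame(taxon1 = rownames(d)[pairs[, 1]],
                       taxon2 = colnames(d)[pairs[, 2]],
                       patristic_distance = d[pairs])
      add(write_csv_report(df, p("Patristic distance.csv"), digits))
      mat <- as.data.frame(d)
      mat <- cbind(taxon = rownames(d), mat)
      add(write_csv_report(mat, p("Patristic distance.matrix.csv"), digits))
    },
    root2tip = {
      r2t <- root_to_tip_lengths(tree)
      df <- data.frame(taxon = names(r2t), root_to_tip = unname(r2t))
      add(write_csv_report(df, p("root-to-tip-branch-length.csv"), digits))
      itol_path <- p("root-to-tip-branch-length.itol.txt")
      write_itol_simplebar(r2t, "Root-to-tip branch length", itol_path)
      add(itol_path)
    },
    evorate = {
      df <- data.frame(tree = stem, evolution_rate = evolution_rate(tree))
      add(write_csv_report(df, p("Evolution rate.csv"), digits))
    },
    unroot = {
      path <- p("unrooted.nwk")
      write_newick(unroot_tree(tree), path)
      add(path)
    },
    polytomy = {
      path <- p("bifurcating.nwk")
      write_newick(resolve_polytomy(tree), path)
      add(path)
    }
  )
  written
}

#' Extract genes from GenBank files and write per-gene FASTA sets
#'
#' Convenience driver: reads the GenBank files, optionally removes redundant
#' records (RefSeq preferred), extracts the selected feature kinds with name
#' unification and writes per-gene FASTA files plus the
#' `name_for_unification.tsv` report.
#'
#' @param gb_files GenBank flat files.
#' @param outdir Output directory.
#' @param code_table NCBI code-table id used for CDS translation fallback.
#' @param kinds Feature kinds to extract.
#' @param dedup Remove redundant (identical-sequence) records first?
#' @param name_map_file Optional alias TSV replacing the bundled map.
#' @param label_template Taxon-label template.
#' @return Invisibly, the `extraction_bundle`.
#' @export
run_extract <- function(gb_files, outdir, code_table = 1,
                        kinds = c("CDS", "tRNA", "rRNA"), dedup = TRUE,
                        name_map_file = NULL,
                        label_template = "{organism}_{accession}") {
  records <- list()
  for (f in gb_files) records <- c(records, read_genbank(f))
  if (dedup) {
    dd <- deduplicate_records(records)
    if (length(dd$removed)) {
      message(sprintf("removed %d redundant record(s): %s",
                      length(dd$removed),
                      paste(vapply(dd$removed, `[[`, "", "accession"),
                            collapse = ", ")))
    }
    records <- dd$kept
  }
  map <- if (is.null(name_map_file)) default_name_map() else {
    read_name_map(name_map_file)
  }
  bundle <- extract_genes(records, map, genetic_code(code_table),
                          kinds = kinds, label_template = label_template)
  write_extraction(bundle, outdir)
  invisible(bundle)
}

#' Concatenate per-gene alignment files into a supermatrix
#'
#' Reads the per-gene alignments (one file per gene, stem = gene name),
#' optionally restricts protein-coding genes to a subset of codon positions,
#' concatenates with `?` filling, and writes the supermatrix in the
#' requested formats together with NEXUS sets and RAxML partition files.
#'
#' @param gene_files Alignment files, one per gene.
#' @param outdir Output directory.
#' @param name Output file stem (default `"supermatrix"`).
#' @param formats Output alignment formats.
#' @param aln_format Input format of the gene files.
#' @param split_codon Optional codon positions to keep, e.g. `c(1, 2)`
#'   (applied to the genes named in `pcg`, or to all genes when `pcg` is
#'   `NULL`).
#' @param pcg Names of protein-coding gene files (stems) for codon handling.
#' @param codon_charsets Emit per-codon-position strided charsets for
#'   protein-coding partitions?
#' @return Invisibly, the `concat_result`.
#' @export
run_concat <- function(gene_files, outdir, name = "supermatrix",
                       formats = c("fasta", "phylip", "nexus"),
                       aln_format = "fasta", split_codon = NULL, pcg = NULL,
                       codon_charsets = FALSE) {
  if (length(gene_files) == 0L) stop("no gene alignment files supplied")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genes <- list()
  for (f in gene_files) {
    genes[[tools::file_path_sans_ext(basename(f))]] <-
      read_alignment(f, aln_format)
  }
  if (!is.null(split_codon)) {
    target <- if (is.null(pcg)) names(genes) else pcg
    for (g in intersect(target, names(genes))) {
      genes[[g]] <- split_codon_sites(genes[[g]], split_codon)
    }
  }
  res <- concatenate(genes)
  for (fmt in formats) {
    ext <- c(fasta = "fasta", phylip = "phy", nexus = "nex")[[fmt]]
    write_alignment(res$matrix, fmt,
                    file.path(outdir, sprintf("%s.%s", name, ext)))
  }
  scheme <- res$scheme
  if (codon_charsets && !is.null(pcg)) {
    scheme <- codon_partition_scheme(scheme, pcg)
  }
  write_partition_scheme(scheme, "nexus_sets",
                         file.path(outdir, sprintf("%s.sets.nex", name)))
  write_partition_scheme(scheme, "raxml",
                         file.path(outdir, sprintf("%s.partition.txt", name)))
  occ <- data.frame(taxon = names(res$occupancy),
                    occupancy = unname(res$occupancy))
  write_csv_report(occ, file.path(outdir, sprintf("%s.occupancy.csv", name)))
  invisible(res)
}
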