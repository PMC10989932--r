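make_fixture_file <- function(..., path = tempfile(fileext = ".gb")) {
  writeLines(paste0(...), path)
  path
}

toy_record <- function(accession = "NC_900001", organism = "Synthia exempli",
                       strandW = "-") {
  genbank_fixture(
    data.frame(
      name = c("COI", "trnW", "16S ribosomal RNA"),
      seq = c("ATGAAATGATAA", "AAGGCCTTAAGGCCTTAAGGCC", "CCGGTTAACCGGTTAA"),
      kind = c("CDS", "tRNA", "rRNA"),
      strand = c("+", strandW, "+"),
      stringsAsFactors = FALSE
    ),
    organism = organism, accession = accession
  )
}

test_that("read_genbank parses records, joins and complements structurally", {
  f <- make_fixture_file(toy_record(), toy_record(accession = "MK000001"))
  recs <- read_genbank(f)
  expect_length(recs, 2L)
  r <- recs[[1]]
  expect_equal(r$accession, "NC_900001")
  expect_equal(r$organism, "Synthia exempli")
  expect_equal(r$lineage, c("Eukaryota", "Synthetica"))
  expect_equal(length(r$features), 3L)

  # complement location captured as strand '-'
  w <- r$features[[2]]
  expect_equal(w$kind, "tRNA")
  expect_equal(w$strand, "-")

  # join() keeps interval order
  gb <- c(
    "LOCUS       TEST 18 bp DNA",
    "ACCESSION   TEST1",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..3,7..9)",
    '                     /gene="dummy"',
    "ORIGIN",
    "        1 atgaaacccg ggtttaaa",
    "//"
  )
  f2 <- tempfile(); writeLines(gb, f2)
  ft <- read_genbank(f2)[[1]]$features[[1]]
  expect_equal(ft$intervals, rbind(c(1L, 3L), c(7L, 9L)))
  expect_equal(ft$strand, "+")

  # coordinate beyond sequence end and missing ORIGIN are rejected
  gb_bad <- sub("join\\(1\\.\\.3,7\\.\\.9\\)", "1..99", gb)
  f3 <- tempfile(); writeLines(gb_bad, f3)
  expect_error(read_genbank(f3), "outside")
  f4 <- tempfile(); writeLines(c(gb[1:5], "//"), f4)
  expect_error(read_genbank(f4), "ORIGIN")
})

test_that("deduplication keeps RefSeq preferentially and is idempotent", {
  f <- make_fixture_file(
    toy_record(accession = "MK123456"),
    toy_record(accession = "NC_000001"),
    toy_record(accession = "OP111111", organism = "Synthia altera", strandW = "+"),
    toy_record(accession = "OP222222", organism = "Synthia altera", strandW = "+")
  )
  recs <- read_genbank(f)
  dd <- deduplicate_records(recs)
  accs <- vapply(dd$kept, `[[`, "", "accession")
  expect_equal(accs, c("NC_000001", "OP111111"))
  expect_equal(vapply(dd$removed, `[[`, "", "accession"),
               c("MK123456", "OP222222"))
  expect_length(dd$kept, 2L)
  expect_equal(length(dd$kept) + length(dd$removed), length(recs))

  # idempotence
  dd2 <- deduplicate_records(dd$kept)
  expect_length(dd2$removed, 0L)
  expect_equal(vapply(dd2$kept, `[[`, "", "accession"), accs)

  # all distinct: nothing removed
  dd3 <- deduplicate_records(recs[c(1, 3)])
  expect_length(dd3$removed, 0L)
})

test_that("gene-name unification is case- and punctuation-insensitive", {
  expect_equal(unify_gene_name("COI"), list(canonical = "cox1", matched = TRUE))
  expect_equal(unify_gene_name("cox1")$canonical, "cox1")
  expect_true(unify_gene_name("Cytochrome c oxidase subunit I")$matched)
  expect_equal(unify_gene_name("16S ribosomal RNA")$canonical, "rrnL")
  expect_equal(unify_gene_name("tRNA-Trp")$canonical, "trnW")
  expect_equal(unify_gene_name("ORF42"), list(canonical = "orf42",
                                              matched = FALSE))
  expect_error(unify_gene_name(""), "empty")

  # user-supplied map overrides
  f <- tempfile()
  writeLines(c("Old Name\tNew Name", "weird-1\tnad1"), f)
  m <- read_name_map(f)
  expect_equal(unify_gene_name("WEIRD 1", m)$canonical, "nad1")
})

test_that("taxon label templates substitute placeholders", {
  rec <- list(organism = "Gyrodactylus salaris", accession = "NC_008815")
  expect_equal(make_taxon_label(rec), "Gyrodactylus_salaris_NC_008815")
  expect_equal(make_taxon_label(rec, "{accession}"), "NC_008815")
  expect_error(make_taxon_label(rec, "{genus}"), "unknown placeholder")
})

test_that("extraction recovers sequences, translates CDS and tallies names", {
  f <- make_fixture_file(toy_record())
  recs <- read_genbank(f)
  b <- extract_genes(recs, code = genetic_code(9))
  expect_setequal(names(b$genes), c("cox1", "trnW", "rrnL"))
  lab <- "Synthia_exempli_NC_900001"
  expect_equal(unname(b$genes$cox1$nt[lab]), "ATGAAATGATAA")
  # table 9: ATG AAA TGA TAA -> M N W, terminal stop stripped
  expect_equal(unname(b$genes$cox1$aa[lab]), "MNW")
  # minus-strand tRNA recovered in forward orientation
  expect_equal(unname(b$genes$trnW$nt[lab]), "AAGGCCTTAAGGCCTTAAGGCC")
  # rRNA has no amino-acid entry
  expect_length(b$genes$rrnL$aa, 0L)
  expect_equal(nrow(b$unmatched), 0L)

  # complement-strand CDS: stored revcomp, extracted forward
  gb <- genbank_fixture(data.frame(name = "nad1", seq = "ATGTTT",
                                   kind = "CDS", strand = "-"),
                        accession = "XX_1")
  f2 <- tempfile(); writeLines(gb, f2)
  r2 <- read_genbank(f2)[[1]]
  expect_equal(substr(r2$sequence, 1, 6), "AAACAT")
  b2 <- extract_genes(list(r2), code = genetic_code(9))
  expect_equal(unname(b2$genes$nad1$nt[[1]]), "ATGTTT")

  # unmatched raw names pass through normalised and are counted
  gb3 <- genbank_fixture(data.frame(name = "ORF42", seq = "ATGAAATAA",
                                    kind = "CDS", strand = "+"),
                         accession = "XX_2")
  f3 <- tempfile(); writeLines(gb3, f3)
  b3 <- extract_genes(read_genbank(f3), code = genetic_code(9))
  expect_equal(b3$unmatched$raw_name, "ORF42")
  expect_equal(b3$unmatched$suggested_name, "orf42")
  expect_equal(b3$unmatched$count, 1L)
  expect_true("orf42" %in% names(b3$genes))
})

test_that("extraction is total: every selected feature lands in a gene set", {
  set.seed(7)
  n_rec <- 4L
  files <- vapply(seq_len(n_rec), function(i) {
    genes <- data.frame(
      name = c("COI", sprintf("ORF%d", i), "tRNA-Phe"),
      seq = c(random_cds(6, genetic_code(9), seed = i),
              random_cds(5, genetic_code(9), seed = 100 + i),
              "AAGGCCTTAAGG"),
      kind = c("CDS", "CDS", "tRNA"),
      strand = "+", stringsAsFactors = FALSE
    )
    f <- tempfile()
    writeLines(genbank_fixture(genes, organism = sprintf("Taxon s%d", i),
                               accession = sprintf("NC_%06d", i)), f)
    f
  }, character(1))
  recs <- unlist(lapply(files, read_genbank), recursive = FALSE)
  b <- extract_genes(recs, code = genetic_code(9))
  n_extracted <- sum(vapply(b$genes, function(g) length(g$nt), integer(1)))
  expect_equal(n_extracted, 3L * n_rec)          # every feature accounted for
  expect_equal(sum(b$unmatched$count), n_rec)    # the ORFs
  expect_length(b$genes$cox1$nt, n_rec)
})

test_that("write_extraction emits per-gene FASTA and the unification report", {
  f <- make_fixture_file(toy_record())
  b <- extract_genes(read_genbank(f), code = genetic_code(9))
  out <- tempfile()
  write_extraction(b, out)
  expect_true(file.exists(file.path(out, "cox1.fasta")))
  expect_true(file.exists(file.path(out, "cox1.aa.fasta")))
  expect_true(file.exists(file.path(out, "name_for_unification.tsv")))
  aa <- read_alignment(file.path(out, "cox1.aa.fasta"), "fasta",
                       alphabet = "amino_acid")
  expect_equal(unname(aa[[1]]), "MNW")
})
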