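worked_tree <- function() parse_newick("((A:1,B:2):1,(C:3,D:4):2);")

test_that("patristic distances match hand sums and the brute-force oracle", {
  d <- patristic_matrix(worked_tree())
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 7)
  expect_equal(d["A", "D"], 8)
  expect_equal(d["B", "C"], 8)
  expect_equal(d["B", "D"], 9)
  expect_equal(d["C", "D"], 7)
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_equal(unname(diag(d)), rep(0, 4))

  expect_equal(unname(patristic_matrix(parse_newick("(A:1,B:2);"))["A", "B"]), 3)

  for (seed in 1:50) {
    tr <- random_fixture_tree(sample(4:10, 1), seed)
    d <- patristic_matrix(tr)
    expect_equal(d, oracle_patristic(tr), tolerance = 1e-12, ignore_attr = TRUE)
    # independent library cross-check
    expect_equal(d[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
    set.seed(seed)
    expect_true(check_four_point(d))
  }

  no_len <- parse_newick("(A,B,C);")
  expect_error(patristic_matrix(no_len), "no branch lengths")
})

test_that("root-to-tip lengths are root path sums and need a rooted tree", {
  r2t <- root_to_tip_lengths(worked_tree())
  expect_equal(r2t, c(A = 2, B = 3, C = 5, D = 6))
  ultra <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(unname(root_to_tip_lengths(ultra)), rep(2, 4))
  expect_error(root_to_tip_lengths(parse_newick("(A:1,B:1,C:1);")), "unrooted")
})

test_that("long-branch scores follow the percent-deviation formula", {
  rep <- lb_scores(worked_tree())
  expect_equal(rep$scores$lb[match(c("A", "B", "C", "D"), rep$scores$taxon)],
               c(-100 / 7, -100 / 21, 100 / 21, 100 / 7),
               tolerance = 1e-9)
  expect_equal(rep$scores$lb[rep$scores$taxon == "A"], -14.2857, tolerance = 1e-4)
  expect_equal(rep$mean_pd_all, mean(c(3, 7, 8, 8, 9, 7)))
  expect_equal(unname(rep$summary["mean"]), 0, tolerance = 1e-12)
  expect_equal(unname(rep$summary["max"]), 100 / 7, tolerance = 1e-9)

  # star tree with equal terminal lengths: all scores zero
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  expect_equal(lb_scores(star)$scores$lb, rep(0, 4), tolerance = 1e-12)

  # sum-to-zero identity on random trees
  for (seed in 1:50) {
    tr <- random_fixture_tree(sample(4:30, 1), seed)
    expect_lt(abs(mean(lb_scores(tr)$scores$lb)), 1e-9)
  }

  zero <- parse_newick("((A:0,B:0):0,C:0);")
  expect_error(lb_scores(zero), "zero")
  expect_error(lb_scores(parse_newick("(A:1,B:1);")), "at least 3")
})

test_that("lb scores and the other tree statistics are rooting-invariant", {
  for (seed in 1:10) {
    tr <- random_fixture_tree(8, seed + 300)
    u <- unroot_tree(tr)
    r <- set_outgroup(tr, sample(tr$tip.label, 1))
    for (f in list(function(x) lb_scores(x)$scores$lb[order(x$tip.label)][1:8],
                   treeness, evolution_rate)) {
      expect_equal(f(u), f(tr), tolerance = 1e-9)
      expect_equal(f(r), f(tr), tolerance = 1e-9)
    }
  }
})

test_that("spurious species flagging uses the at-least-threshold-times-median rule", {
  tr <- worked_tree()
  sp <- spurious_species(tr)             # default threshold 20
  expect_equal(sp$threshold, 20)
  expect_equal(sp$median_length, 2)      # sorted lengths {1,1,2,2,3,4}
  expect_length(sp$flagged, 0L)

  sp2 <- spurious_species(tr, threshold = 1.5)
  expect_setequal(sp2$flagged, c("C", "D"))  # cutoff 3; 3 >= 3 ("at least")

  # boundary: terminal exactly at threshold x median is flagged
  tb <- parse_newick("((A:1,B:1):1,(C:1,D:2):1);")
  expect_true("D" %in% spurious_species(tb, threshold = 2)$flagged)

  expect_error(spurious_species(tr, threshold = 0), "positive")
  expect_error(spurious_species(parse_newick("((A:0,B:0):0,C:0);")),
               "degenerate")
})

test_that("treeness is the internal fraction of total branch length", {
  expect_equal(treeness(worked_tree()), 3 / 13)
  expect_equal(treeness(parse_newick("(A:1,B:1,C:1);")), 0)
  # lengthening an internal edge strictly increases treeness
  tr <- worked_tree()
  internal <- which(tr$edge[, 2] > ape::Ntip(tr))
  tr2 <- tr; tr2$edge.length[internal[1]] <- tr2$edge.length[internal[1]] + 1
  expect_gt(treeness(tr2), treeness(tr))
  for (seed in 1:30) {
    v <- treeness(random_fixture_tree(sample(3:20, 1), seed))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("composition profiles weight degenerate codes fractionally", {
  p <- composition_profile(aln_matrix(c(x = "Y", y = "C"),
                                      alphabet = "nucleotide"))
  expect_equal(p$counts["C", ], c(x = 0.5, y = 1))
  expect_equal(p$counts["T", ], c(x = 0.5, y = 0))
  expect_equal(p$t, 1L)

  pD <- composition_profile(aln_matrix(c(x = "D"), alphabet = "nucleotide"))
  expect_equal(pD$counts[c("A", "G", "T"), 1], c(A = 1, G = 1, T = 1) / 3)
  expect_equal(unname(pD$counts["C", 1]), 0)

  pN <- composition_profile(aln_matrix(c(x = "N"), alphabet = "nucleotide"))
  expect_equal(unname(pN$counts[, 1]), rep(0.25, 4))

  # gaps and '?' contribute nothing; t still counts all columns
  pg <- composition_profile(aln_matrix(c(x = "-?", y = "--"),
                                       alphabet = "nucleotide"))
  expect_equal(sum(pg$counts), 0)
  expect_equal(pg$t, 2L)

  # amino-acid two-fold codes
  pB <- composition_profile(aln_matrix(c(x = "B"), alphabet = "amino_acid"))
  expect_equal(unname(pB$counts["D", 1]), 0.5)
  expect_equal(unname(pB$counts["N", 1]), 0.5)
  pX <- composition_profile(aln_matrix(c(x = "X"), alphabet = "amino_acid"))
  expect_equal(unname(pX$counts[, 1]), rep(1 / 20, 20))
})

test_that("RCV matches closed forms and decomposes additively", {
  expect_equal(rcv(aln_matrix(c(A = "AAAA", B = "TTTT")))$rcv, 1)
  expect_equal(rcv(aln_matrix(c(A = "ACGT", B = "ACGT")))$rcv, 0)
  expect_equal(rcv(aln_matrix(c(x = "Y", y = "C"), alphabet = "nucleotide"))$rcv,
               0.5)

  for (seed in 1:20) {
    a <- random_fixture_aln(sample(2:8, 1), 40, seed)
    r <- rcv(a)
    expect_equal(sum(r$per_taxon), r$rcv, tolerance = 1e-12)
    expect_gte(r$rcv, 0)

    # invariant to column permutation
    set.seed(seed)
    perm <- sample(aln_ncol(a))
    permuted <- vapply(a, function(s) {
      paste(strsplit(s, "")[[1]][perm], collapse = "")
    }, character(1))
    ap <- aln_matrix(permuted, alphabet = aln_alphabet(a))
    expect_equal(rcv(ap)$rcv, r$rcv, tolerance = 1e-12)

    # invariant to horizontal duplication (t -> 2t)
    doubled <- aln_matrix(paste0(unclass(a), unclass(a)),
                          labels = names(a), alphabet = aln_alphabet(a))
    expect_equal(rcv(doubled)$rcv, r$rcv, tolerance = 1e-12)
  }
  expect_error(rcv(aln_matrix(c(A = "ACGT"))), "2 taxa")
})

test_that("signal-to-noise is treeness over RCV with clean degenerate errors", {
  tr <- worked_tree()
  aln <- aln_matrix(c(A = "AAAA", B = "TTTT", C = "AAAA", D = "TTTT"))
  s <- signal_to_noise(tr, aln)
  expect_equal(s$treeness, 3 / 13)
  expect_equal(s$signal_to_noise, s$treeness / s$rcv)

  # scale invariance of treeness makes the ratio invariant to branch scaling
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 2
  expect_equal(signal_to_noise(tr2, aln)$signal_to_noise, s$signal_to_noise)

  same <- aln_matrix(c(A = "AC", B = "AC", C = "AC", D = "AC"))
  expect_error(signal_to_noise(tr, same), "undefined|zero")
  expect_error(signal_to_noise(tr, aln_matrix(c(A = "AC", B = "AC"))),
               "absent")
})

test_that("pairwise differences use pairwise deletion of non-states", {
  ps <- pairwise_sequence_stats(aln_matrix(c(a = "ACGT", b = "ACGA")))
  expect_equal(ps$records$difference, 0.25)
  expect_equal(ps$records$identity, 0.75)
  expect_equal(ps$records$compared, 4L)

  ps2 <- pairwise_sequence_stats(aln_matrix(c(a = "AC-T", b = "ACGT")))
  expect_equal(ps2$records$compared, 3L)
  expect_equal(ps2$records$difference, 0)

  # ambiguity codes excluded entirely
  ps3 <- pairwise_sequence_stats(aln_matrix(c(a = "ANGT", b = "ACGT")))
  expect_equal(ps3$records$compared, 3L)

  # identical rows
  ps4 <- pairwise_sequence_stats(aln_matrix(c(a = "ACGT", b = "ACGT")))
  expect_equal(ps4$records$difference, 0)
  expect_equal(ps4$records$identity, 1)

  # zero-overlap pairs are flagged
  ps5 <- pairwise_sequence_stats(aln_matrix(c(a = "AC--", b = "--GT")))
  expect_equal(nrow(ps5$excluded_pairs), 1L)

  # identity + difference = 1 on compared sites, symmetry of the matrix
  for (seed in 1:10) {
    a <- random_fixture_aln(sample(3:6, 1), 50, seed)
    ps <- pairwise_sequence_stats(a)
    ok <- ps$records$compared > 0
    expect_equal(ps$records$difference[ok] + ps$records$identity[ok],
                 rep(1, sum(ok)))
    expect_equal(ps$p_distance, t(ps$p_distance))
  }
})

test_that("saturation regression recovers exact linear relations", {
  # synthetic: 6 leaves on a caterpillar, alignment engineered is unnecessary -
  # feed the regression directly through its fitting helper via known points
  tr <- parse_newick("((A:1,B:2):1,(C:3,D:4):2);")
  aln <- aln_matrix(c(A = "AAAA", B = "AAAT", C = "AATT", D = "ATTT"))
  res <- saturation_regression(tr, aln)
  expect_s3_class(res, "saturation_result")
  expect_equal(res$n_pairs, 6L)
  expect_gte(res$r2, 0); expect_lte(res$r2, 1)

  # perfect linearity: y = 0.1 x with intercept 0
  fitted <- phylokit:::fit_saturation(x = c(1, 2, 3, 4), y = c(0.1, 0.2, 0.3, 0.4),
                                      fit = "ols_intercept")
  expect_equal(fitted$slope, 0.1, tolerance = 1e-12)
  expect_equal(fitted$intercept, 0, tolerance = 1e-12)
  expect_equal(fitted$r2, 1, tolerance = 1e-12)

  # constant y: slope 0, r2 reported as 0
  flat <- phylokit:::fit_saturation(x = c(1, 2, 3), y = c(0.2, 0.2, 0.2),
                                    fit = "ols_intercept")
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0)

  # through-origin mode
  to <- phylokit:::fit_saturation(x = c(1, 2, 4), y = c(0.1, 0.2, 0.4),
                                  fit = "through_origin")
  expect_equal(to$slope, 0.1, tolerance = 1e-12)
  expect_equal(to$intercept, 0)
  expect_equal(to$r2, 1, tolerance = 1e-12)

  expect_error(saturation_regression(parse_newick("(A:1,B:1);"),
                                     aln_matrix(c(A = "AC", B = "AC"))),
               "3 usable")
})

test_that("the slope is recovered near 1 at low divergence", {
  # pairwise distances of ~0.1 substitutions/site or less: the JC curve is
  # still near-linear, so the regression should recover slope ~ 1
  tr <- simulate_yule_tree(10, birth = 4, scale = 0.05, seed = 808)
  a <- evolve_alignment(tr, 10000, seed = 809)
  s <- saturation_regression(tr, a)
  expect_gt(s$slope, 0.85)
  expect_lt(s$slope, 1.05)
  expect_gt(s$r2, 0.8)
})

test_that("higher divergence lowers the saturation slope on simulated data", {
  tr <- simulate_yule_tree(12, birth = 4, seed = 909)
  a_low <- evolve_alignment(tr, 2000, seed = 910)
  tr_hi <- tr; tr_hi$edge.length <- tr$edge.length * 10
  a_hi <- evolve_alignment(tr_hi, 2000, seed = 910)
  s_low <- saturation_regression(tr, a_low)
  s_hi <- saturation_regression(tr_hi, a_hi)
  expect_lt(s_hi$slope, s_low$slope)
  expect_lt(s_hi$r2 - 1e-12, 1)
})

test_that("evolution rate is total length per terminal and scales linearly", {
  expect_equal(evolution_rate(worked_tree()), 13 / 4)
  expect_equal(evolution_rate(parse_newick("(A:2,B:2,C:2);")), 2)
  tr <- random_fixture_tree(10, 42)
  tr3 <- tr; tr3$edge.length <- tr$edge.length * 3
  expect_equal(evolution_rate(tr3), 3 * evolution_rate(tr))
  expect_error(evolution_rate(parse_newick("(A,B,C);")), "branch length")
})
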