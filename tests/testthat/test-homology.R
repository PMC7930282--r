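B62 <- venom_blosum62()

test_that("local alignment matches hand-computed BLOSUM62 scores", {
  # P7 + A4 + W11 + H8 + E5 + A4 + E5 = 44
  expect_equal(smith_waterman("PAWHEAE", "PAWHEAE")$score, 44)
  # A-G scores 0: no positive-scoring local alignment exists
  expect_equal(smith_waterman("AAAA", "GGGG")$score, 0)
  expect_equal(smith_waterman("AAAA", "")$score, 0)
  expect_equal(smith_waterman("", "")$score, 0)
})

test_that("X scores zero against every residue", {
  expect_true(all(B62["X", ] == 0))
  expect_equal(smith_waterman("XXXX", "WWWW")$score, 0)
})

test_that("self-alignment score equals the sum of diagonal matrix entries", {
  set.seed(17)
  aa <- rownames(B62)[1:20]
  for (rep in 1:10) {
    s <- paste(sample(aa, sample(5:40, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman(s, s)$score,
                 sum(diag(B62)[match(strsplit(s, "")[[1]], rownames(B62))]))
  }
})

test_that("alignment scores are symmetric for a symmetric matrix", {
  set.seed(19)
  aa <- rownames(B62)[1:20]
  for (rep in 1:10) {
    a <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:30, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
    expect_equal(align_pair(a, b, type = "global")$score,
                 align_pair(b, a, type = "global")$score)
  }
})

test_that("local scores equal exhaustive enumeration over all alignments", {
  # exhaustive over every sequence pair on a 2-letter alphabet (lengths
  # 1-3), then randomized 4-letter pairs up to length 5
  words <- all_words(c("A", "W"), 3L)
  for (a in words) for (b in words)
    expect_equal(smith_waterman(a, b)$score, bf_local_score(a, b, B62))
  set.seed(29)
  ab <- c("A", "C", "D", "W")
  for (rep in 1:25) {
    a <- paste(sample(ab, sample(2:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(ab, sample(2:5, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, bf_local_score(a, b, B62))
  }
})

test_that("global scores equal exhaustive enumeration", {
  set.seed(31)
  ab <- c("A", "C", "D", "W")
  for (rep in 1:20) {
    a <- sample(ab, sample(1:5, 1), replace = TRUE)
    b <- sample(ab, sample(1:5, 1), replace = TRUE)
    expect_equal(align_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                            type = "global")$score,
                 bf_global_score(a, b, B62))
  }
})

test_that("scores agree with an independent alignment library", {
  set.seed(37)
  aa <- rownames(B62)[1:20]
  for (rep in 1:15) {
    a <- paste(sample(aa, sample(20:60, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(20:60, 1), replace = TRUE), collapse = "")
    # Biostrings charges gapOpening + gapExtension * k for a length-k gap;
    # open 10 / extend 1 therefore equals this package's 11 + (k - 1)
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = B62, gapOpening = 10, gapExtension = 1)
    expect_equal(smith_waterman(a, b)$score, Biostrings::score(ref))
  }
})

test_that("reference search reports identity, coverage and best hits", {
  refs <- c(r1 = "MKWVTFISLLLLFSSAYSRGVFRRDAQAEKLV", r2 = "PPPPPPPPPPPP")
  hits <- search_reference(c(q1 = refs[["r1"]]), refs)
  expect_equal(hits$reference_id[hits$best], "r1")
  expect_equal(hits$percent_identity[hits$best], 100)
  expect_equal(hits$query_coverage[hits$best], 1)

  set.seed(43)
  rnd <- paste(sample(rownames(B62)[1:20], 40, replace = TRUE), collapse = "")
  none <- search_reference(c(q = rnd), refs)
  expect_equal(nrow(none), 0L)
  expect_equal(attr(none, "unmatched"), "q")
  expect_warning(search_reference(c(q = rnd), character(0)), "empty reference")
})

test_that("tightening any threshold never adds matches", {
  sim <- cached_sim()
  pipe <- cached_pipeline()
  q <- setNames(pipe$secretome$orf_seq, pipe$secretome$protein_id)[1:10]
  base <- search_reference(q, sim$reference)
  key <- function(h) paste(h$query_id, h$reference_id)
  for (args in list(list(min_identity = 60), list(min_coverage = 0.9),
                    list(min_score = 200))) {
    tight <- do.call(search_reference, c(list(q, sim$reference), args))
    expect_true(all(key(tight) %in% key(base)))
  }
})

test_that("planted homologs are matched to their reference partners", {
  cfg <- generator_config(homolog_identity_range = c(0.6, 0.6), seed = 21L,
                          n_contigs = 60L)
  sim <- cached_sim(cfg)
  ven <- sim$truth[sim$truth$is_venom, ]
  mature <- substr(ven$protein, ven$signal_len + 1L, nchar(ven$protein))
  hits <- search_reference(setNames(mature, ven$contig_id), sim$reference)
  best <- hits[hits$best, ]
  expect_setequal(best$query_id, ven$contig_id)
  expect_equal(best$reference_id[match(ven$contig_id, best$query_id)],
               paste0("ref_", ven$contig_id))
})

test_that("planted reference identity is recovered by global alignment", {
  cfg <- generator_config(homolog_identity_range = c(0.6, 0.6), seed = 21L,
                          n_contigs = 60L)
  sim <- cached_sim(cfg)
  ven <- sim$truth[sim$truth$is_venom, ]
  for (i in seq_len(nrow(ven))) {
    mature <- substr(ven$protein[i], ven$signal_len[i] + 1L,
                     nchar(ven$protein[i]))
    ref <- as.character(sim$reference)[[paste0("ref_", ven$contig_id[i])]]
    al <- align_pair(mature, ref, type = "global")
    expect_equal(al$identity, 0.6, tolerance = 0.05)
    expect_equal(al$identity, ven$homolog_identity[i], tolerance = 1e-9)
  }
})

test_that("catalytic-triad detection reads the canonical columns", {
  canon <- make_canonical_protease()
  self <- detect_catalytic_triad(canon$seq, canon)
  expect_equal(unlist(self, use.names = FALSE),
               rep("canonical", 3L))

  # serine replaced by arginine at both serine columns
  mut <- strsplit(canon$seq, "")[[1]]
  mut[canon$positions$S] <- "R"
  tr <- detect_catalytic_triad(paste(mut, collapse = ""), canon)
  expect_equal(tr$ser_state, "substituted:R")
  expect_equal(tr$his_state, "canonical")

  # deleting the region around column 70 gaps the histidine out
  del <- paste(strsplit(canon$seq, "")[[1]][-(55:85)], collapse = "")
  tr2 <- detect_catalytic_triad(del, canon)
  expect_equal(tr2$his_state, "undetermined")

  expect_error(detect_catalytic_triad("MKV", list(seq = "MKV")), "lacks")
})
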