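test_that("a classic secretory N-terminus is called with its cleavage site", {
  # M K W V T F I S L L L L F S S A Y S R G V F R R: candidate sites with
  # small -3/-1 residues are 16, 18 and 20; all share the best h-window
  # FISLLLLF (mean KD 3.0625), so the smallest site wins
  call <- score_signal_peptide("MKWVTFISLLLLFSSAYSRGVFRR")
  expect_true(call$is_secreted)
  expect_equal(call$cleavage_site, 16L)
  expect_equal(call$score, 3.0625)
})

test_that("sequences without a hydrophobic core are negative", {
  acidic <- paste0("M", paste(rep(c("D", "E"), 12), collapse = ""))
  call <- score_signal_peptide(acidic)
  expect_false(call$is_secreted)
  expect_true(is.na(call$cleavage_site))
})

test_that("short and 5'-incomplete inputs yield no-calls, not negatives", {
  short <- score_signal_peptide("MKWVTFISLLLL")
  expect_true(is.na(short$is_secreted))
  expect_equal(short$no_call_reason, "too_short")

  inc <- score_signal_peptide("MKWVTFISLLLLFSSAYSRGVFRR",
                              completeness = "incomplete_5prime")
  expect_true(is.na(inc$is_secreted))
  expect_equal(inc$no_call_reason, "incomplete_5prime")
})

test_that("a negatively charged n-region blocks the call", {
  # same architecture but the n-region carries two acidic residues
  pos <- "MKRLLLLLLLLSQAGASAKDDDDDD"
  neg <- "MDELLLLLLLLSQAGASAKKKKKKK"
  expect_true(score_signal_peptide(pos)$is_secreted)
  expect_false(score_signal_peptide(neg)$is_secreted)
})

test_that("secretome filtering keeps exactly the positive calls and is idempotent", {
  sim <- cached_sim()
  db <- translate_contigs(sim$contigs)
  m <- map_peptides(sim$peptides$peptide, db)
  cand <- infer_identified_contigs(m, db)
  calls <- signal_peptide_calls(cand)
  sec <- filter_secretome(cand, calls)
  expect_true(all(sec$protein_id %in% cand$protein_id))
  pos <- calls$protein_id[!is.na(calls$is_secreted) & calls$is_secreted]
  expect_setequal(sec$protein_id, intersect(cand$protein_id, pos))
  sec2 <- filter_secretome(sec, calls)
  expect_equal(sec2$protein_id, sec$protein_id)
  # order-independence
  shuf <- cand[rev(seq_len(nrow(cand))), ]
  expect_setequal(filter_secretome(shuf, calls)$protein_id, sec$protein_id)
  expect_error(filter_secretome(cand, calls[-1L, ]), "without a")
})

test_that("the retained secretome equals planted secreted x identified", {
  cfg <- generator_config(contaminant_peptide_rate = 0, seed = 13L)
  sim <- cached_sim(cfg)
  db <- translate_contigs(sim$contigs)
  cand <- infer_identified_contigs(map_peptides(sim$peptides$peptide, db), db)
  sec <- filter_secretome(cand, signal_peptide_calls(cand))
  planted <- sim$truth$contig_id[sim$truth$is_secreted]
  expect_setequal(sec$contig_id, intersect(planted, cand$contig_id))
})

test_that("external signal-peptide calls can replace the heuristic", {
  cand <- data.frame(protein_id = c("c12|frame=+1", "c13|frame=+2"),
                     contig_id = c("c12", "c13"), frame = c("+1", "+2"),
                     orf_seq = c("MKWVTFISLLLLFSSAYSRGVFRR", "MDDDDD"),
                     completeness = "complete", stringsAsFactors = FALSE)
  ext <- data.frame(protein_id = c("c12|frame=+1", "c13|frame=+2"),
                    is_secreted = c("YES", "NO"),
                    cleavage_site = c(19L, NA))
  calls <- import_external_sp_calls(ext, cand)
  expect_equal(calls$is_secreted, c(TRUE, FALSE))
  expect_equal(calls$cleavage_site, c(19L, NA))
  expect_equal(unique(calls$provenance), "external")
  expect_equal(filter_secretome(cand, calls)$protein_id, "c12|frame=+1")

  bad_id <- data.frame(protein_id = "c99|frame=+1", is_secreted = "YES")
  expect_error(import_external_sp_calls(bad_id, cand), "unknown")
  bad_flag <- data.frame(protein_id = "c12|frame=+1", is_secreted = "MAYBE")
  expect_error(import_external_sp_calls(bad_flag, cand), "row 1")
})

test_that("external import reproduces the heuristic's retained set bit for bit", {
  sim <- cached_sim()
  db <- translate_contigs(sim$contigs)
  cand <- infer_identified_contigs(map_peptides(sim$peptides$peptide, db), db)
  calls <- signal_peptide_calls(cand)
  keep <- !is.na(calls$is_secreted)
  ext <- data.frame(protein_id = calls$protein_id[keep],
                    is_secreted = ifelse(calls$is_secreted[keep], "YES", "NO"),
                    cleavage_site = calls$cleavage_site[keep])
  # no-call candidates must still be covered: give them explicit NO rows?
  # no -- they are excluded either way, so restrict to called candidates
  cand2 <- cand[cand$protein_id %in% ext$protein_id, ]
  imported <- import_external_sp_calls(ext, cand2)
  expect_setequal(filter_secretome(cand2, imported)$protein_id,
                  filter_secretome(cand, calls)$protein_id)
})

test_that("the heuristic recovers planted signal-peptide truth", {
  sens <- spec <- numeric(3)
  for (s in 1:3) {
    tr <- generate_transcriptome(generator_config(seed = 300L + s))$truth
    pos <- vapply(tr$protein,
                  function(p) isTRUE(score_signal_peptide(p)$is_secreted), TRUE)
    sens[s] <- mean(pos[tr$is_secreted])
    spec[s] <- mean(!pos[!tr$is_secreted])
  }
  expect_gte(mean(sens), 0.90)
  expect_gte(mean(spec), 0.90)
})
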