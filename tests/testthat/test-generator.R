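test_that("configuration validation rejects out-of-range parameters", {
  expect_error(generator_config(secreted_fraction = 1.2), "fractions")
  expect_error(generator_config(n_contigs = 0), "n_contigs")
  expect_error(generator_config(homolog_identity_range = c(0.9, 0.6)),
               "interval")
  expect_error(generator_config(qpcr_efficiency_range = c(0, 1)), "0, 1.1")
  expect_error(generator_config(count_dispersion = -1), "non-negative")
})

test_that("contig and secreted counts follow the configured fractions exactly", {
  cfg <- generator_config(n_contigs = 300L, secreted_fraction = 0.2, seed = 7L)
  sim <- cached_sim(cfg)
  expect_length(sim$contigs, 300L)
  expect_equal(nrow(sim$truth), 300L)
  expect_equal(sum(sim$truth$is_secreted), round(0.2 * 300))
  expect_equal(sum(sim$truth$is_venom),
               round(cfg$venom_fraction_of_secreted * round(0.2 * 300)))
})

test_that("identical config and seed give byte-identical FASTA outputs", {
  cfg <- generator_config(n_contigs = 40L, seed = 31L)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_venom_study(cfg), d1)
  write_simulation(simulate_venom_study(cfg), d2)
  for (f in c("contigs.fasta", "reference_venom.fasta", "peptides.tsv",
              "counts.tsv", "qpcr.csv", "annotations.tsv", "truth.tsv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("truth-table invariants hold", {
  sim <- cached_sim()
  tr <- sim$truth
  expect_true(all(tr$is_secreted[tr$is_venom]))
  expect_true(all(!is.na(tr$homolog_identity[tr$is_venom])))
  expect_true(all(is.na(tr$homolog_identity[!tr$is_venom])))
  expect_true(all(tr$orf_start >= 0 &
                    tr$orf_end <= Biostrings::width(sim$contigs)))
  expect_true(all((tr$orf_end - tr$orf_start) %% 3L == 0L))
  expect_true(all(tr$expression_level > 0))
  # the ORF span transcribes to the planted protein on the stated strand
  for (i in sample(nrow(tr), 10)) {
    cds <- Biostrings::subseq(sim$contigs[[tr$contig_id[i]]],
                              tr$orf_start[i] + 1L, tr$orf_end[i])
    if (tr$strand[i] == "-") cds <- Biostrings::reverseComplement(cds)
    expect_equal(as.character(Biostrings::translate(cds)), tr$protein[i])
  }
})

test_that("planted signal peptides satisfy the secretome rule by construction", {
  sim <- cached_sim()
  tr <- sim$truth
  for (i in which(tr$is_secreted)) {
    call <- score_signal_peptide(tr$protein[i])
    expect_true(call$is_secreted)
    expect_true(call$cleavage_site >= 15 && call$cleavage_site <= 35)
  }
})

test_that("zero-mutation references equal the planted mature proteins", {
  cfg <- generator_config(homolog_identity_range = c(1, 1), n_contigs = 40L,
                          n_decoy_refs = 0L, seed = 17L)
  sim <- cached_sim(cfg)
  ven <- sim$truth[sim$truth$is_venom, ]
  refs <- as.character(sim$reference)
  expect_length(refs, nrow(ven))
  for (i in seq_len(nrow(ven))) {
    mature <- substr(ven$protein[i], ven$signal_len[i] + 1L,
                     nchar(ven$protein[i]))
    expect_equal(refs[[paste0("ref_", ven$contig_id[i])]], mature)
  }
  expect_equal(sim$truth$homolog_identity[sim$truth$is_venom],
               rep(1, nrow(ven)))
})

test_that("an empty venom fraction leaves only decoys in the reference set", {
  cfg <- generator_config(venom_fraction_of_secreted = 0, n_contigs = 30L,
                          n_decoy_refs = 3L, seed = 19L)
  sim <- cached_sim(cfg)
  expect_length(sim$reference, 3L)
  expect_true(all(grepl("^decoy_", names(sim$reference))))
})

test_that("peptide sampling honours depth and the contaminant construction", {
  base <- generate_transcriptome(generator_config(seed = 23L, n_contigs = 50L))
  cfg0 <- generator_config(peptide_sampling_depth = 0, seed = 23L,
                           n_contigs = 50L)
  expect_equal(nrow(sample_peptides(base, cfg0)), 0L)

  cfg_clean <- generator_config(contaminant_peptide_rate = 0, seed = 23L,
                                n_contigs = 50L)
  peps <- sample_peptides(base, cfg_clean)
  expect_false(any(peps$is_contaminant))
  digests <- lapply(base$truth$protein, function(p) digest_protein(p)$peptide)
  names(digests) <- base$truth$contig_id
  for (j in sample(nrow(peps), 30))
    expect_true(peps$peptide[j] %in% digests[[peps$source_contig[j]]])

  cfg_dirty <- generator_config(contaminant_peptide_rate = 0.2, seed = 23L,
                                n_contigs = 50L)
  dirty <- sample_peptides(base, cfg_dirty)
  cont <- dirty$peptide[dirty$is_contaminant]
  expect_gt(length(cont), 0L)
  db_k <- chartr("I", "L", as.character(translate_contigs(base$contigs)))
  for (pep in cont)
    expect_false(any(grepl(chartr("I", "L", pep), db_k, fixed = TRUE)))
})

test_that("counts are overdispersed around expression with exact degenerate limit", {
  base <- generate_transcriptome(generator_config(seed = 29L, n_contigs = 50L))
  cfg0 <- generator_config(count_dispersion = 0, seed = 29L, n_contigs = 50L)
  c0 <- simulate_counts(base, cfg0)
  expect_equal(c0$count, as.integer(round(base$truth$expression_level)))
  expect_equal(attr(c0, "N"), sum(c0$count))

  zero <- base
  zero$truth$expression_level <- 0
  cz <- simulate_counts(zero, cfg0)
  expect_true(all(cz$count == 0))
  expect_true(attr(cz, "zero_library"))

  cfg <- generator_config(seed = 29L, n_contigs = 50L)
  expect_identical(simulate_counts(base, cfg)$count,
                   simulate_counts(base, cfg)$count)
})

test_that("the qPCR table encodes efficiency, fold change and replication", {
  sim <- cached_sim()
  q <- sim$qpcr
  expect_setequal(unique(q$group), c("body", "venom_gland"))
  expect_equal(sort(unique(q$dilution)), c(0.01, 0.1, 1))
  expect_equal(max(q$bio_rep), 3L)
  expect_equal(max(q$tech_rep), 3L)
  truth <- attr(q, "qpcr_truth")
  expect_equal(truth$fold[truth$gene %in% c("GAPDH", "beta-tubulin")], c(1, 1))
  expect_equal(nrow(q), length(unique(q$gene)) * 2 * 3 * 3 * 3)
})
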