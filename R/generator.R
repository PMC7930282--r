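# Synthetic venom-gland study generator.
#
# Produces a miniature, fully ground-truthed venom-gland dataset: contigs
# with planted ORFs, a planted secreted fraction carrying constructed
# signal peptides, homologs of the planted venom proteins at controlled
# identity, annotation descriptions with or without the venom/toxin
# keywords, tryptic-peptide observations sampled by expression level,
# overdispersed read counts, and dilution-series Ct values with known
# efficiencies and fold changes.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration for the synthetic venom-gland study
#'
#' The defaults define the study conditions every downstream test and
#' recovery analysis runs under: 300 contigs, a 20% secreted fraction of
#' which half are venom proteins with reference homologs planted at
#' 60--90% identity, tryptic-peptide sampling at an expected depth of 10
#' peptides per expressed protein with 5% contaminant peptides,
#' negative-binomial read counts, and qPCR efficiencies of 0.9--1.0.
#'
#' @param n_contigs Number of contigs (>= 1).
#' @param secreted_fraction Fraction of contigs whose planted protein
#'   carries a signal peptide.
#' @param venom_fraction_of_secreted Fraction of secreted proteins with
#'   a homolog planted in the reference venom set.
#' @param homolog_identity_range Interval in \[0, 1\]: target global
#'   identity of each planted reference homolog.
#' @param peptide_sampling_depth Expected observed peptides per protein
#'   of average expression.
#' @param contaminant_peptide_rate Fraction of the observed peptide list
#'   that is contaminant (matching no contig).
#' @param count_dispersion Negative-binomial overdispersion phi
#'   (variance = mu + phi mu^2); 0 gives deterministic rounded counts.
#' @param qpcr_efficiency_range Interval in (0, 1.1\]: per-gene qPCR
#'   amplification efficiency.
#' @param qpcr_noise_sd Technical Ct noise (cycles).
#' @param qpcr_fold_change_range Venom-gland versus body fold change
#'   planted for venom genes.
#' @param n_qpcr_targets Number of venom genes assayed by qPCR.
#' @param n_decoy_refs Unrelated decoy entries added to the reference
#'   set.
#' @param protein_length_range Planted protein length (residues).
#' @param utr_length_range Untranslated flank length (nucleotides).
#' @param unannotated_fraction Fraction of non-venom contigs left
#'   without a description.
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_contigs = 300L,
                             secreted_fraction = 0.2,
                             venom_fraction_of_secreted = 0.5,
                             homolog_identity_range = c(0.6, 0.9),
                             peptide_sampling_depth = 10,
                             contaminant_peptide_rate = 0.05,
                             count_dispersion = 0.3,
                             qpcr_efficiency_range = c(0.9, 1.0),
                             qpcr_noise_sd = 0.15,
                             qpcr_fold_change_range = c(4, 64),
                             n_qpcr_targets = 10L,
                             n_decoy_refs = 5L,
                             protein_length_range = c(80L, 200L),
                             utr_length_range = c(0L, 30L),
                             unannotated_fraction = 0.1,
                             seed = 1L) {
  frac_ok <- function(x) length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
  if (!frac_ok(secreted_fraction) || !frac_ok(venom_fraction_of_secreted) ||
      !frac_ok(contaminant_peptide_rate) || !frac_ok(unannotated_fraction))
    stop("fractions must lie in [0, 1]")
  if (n_contigs < 1L) stop("n_contigs must be >= 1")
  if (length(homolog_identity_range) != 2L ||
      any(homolog_identity_range < 0 | homolog_identity_range > 1) ||
      diff(homolog_identity_range) < 0)
    stop("homolog_identity_range must be an interval in [0, 1]")
  if (any(qpcr_efficiency_range <= 0 | qpcr_efficiency_range > 1.1))
    stop("qpcr_efficiency_range must lie in (0, 1.1]")
  if (peptide_sampling_depth < 0 || count_dispersion < 0 || qpcr_noise_sd < 0)
    stop("depth, dispersion and noise must be non-negative")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 10L)
    stop("seed must be a non-negative 32-bit integer")
  structure(as.list(environment())[c(
    "n_contigs", "secreted_fraction", "venom_fraction_of_secreted",
    "homolog_identity_range", "peptide_sampling_depth",
    "contaminant_peptide_rate", "count_dispersion",
    "qpcr_efficiency_range", "qpcr_noise_sd", "qpcr_fold_change_range",
    "n_qpcr_targets", "n_decoy_refs", "protein_length_range",
    "utr_length_range", "unannotated_fraction", "seed")],
    class = "generator_config")
}

.VENOM_DESCRIPTIONS <- c(
  "venom serine protease precursor", "venom acid phosphatase",
  "venom allergen 5-like", "kazal-type serine protease inhibitor venom protein",
  "plancitoxin-like venom nuclease", "venom carboxylesterase clade B",
  "venom protein U precursor", "venom metalloprotease",
  "venom trypsin-like protease", "toxin-like cysteine-rich peptide")

.HOUSE_DESCRIPTIONS <- c(
  "heat shock protein 70", "ribosomal protein L4 -like",
  "elongation factor 1-alpha", "actin, cytoplasmic",
  "glyceraldehyde-3-phosphate dehydrogenase", "cytochrome P450 6k1",
  "ATP synthase subunit beta", "tubulin alpha chain",
  "protein disulfide-isomerase A3", "odorant receptor 13a")

.SECRETED_NONVENOM_DESCRIPTIONS <- c(
  "serine protease 33 isoform X2", "trypsin-like protease",
  "carboxylesterase clade B member 2 precursor", "chitotriosidase-1",
  "lipase 3-like", "pancreatic triacylglycerol lipase",
  "serpin 5 precursor", "cathepsin L", "alpha-amylase-like",
  "ferritin precursor")

# a synthetic molecular-function ontology subset used for GO annotation
.MINI_GO_FILE <- function()
  system.file("extdata", "mini_go.obo", package = "venomics")

#' The bundled miniature molecular-function ontology
#' @return An `ontology` object (see [read_obo()]).
#' @export
venom_mini_ontology <- function() read_obo(.MINI_GO_FILE())

# reverse-translate an amino-acid sequence with uniformly sampled codons
.reverse_translate <- function(protein, syn) {
  res <- strsplit(protein, "", fixed = TRUE)[[1L]]
  flat <- unlist(syn, use.names = FALSE)
  sizes <- lengths(syn)
  off <- setNames(cumsum(c(0L, sizes[-length(sizes)])), names(syn))
  pick <- off[res] + ceiling(runif(length(res)) * sizes[res])
  paste(flat[pick], collapse = "")
}

# mature-region residues as K/R-terminated blocks of 8-18 residues, so
# every planted protein yields fully-cleaved tryptic fragments within
# the observable 7-35 residue range
.random_mature <- function(len) {
  if (len <= 0L) return(character(0))
  out <- character(0)
  while (length(out) < len) {
    block <- sample(setdiff(.AA20, c("K", "R")), sample(8:18, 1L),
                    replace = TRUE)
    out <- c(out, block, sample(c("K", "R"), 1L))
  }
  out[seq_len(len)]
}

.random_protein <- function(len, secreted) {
  if (secreted) {
    n_len <- sample(2:4, 1L)   # M + positively charged n-region
    h_len <- sample(8:11, 1L)  # hydrophobic core
    c_len <- sample(5:6, 1L)   # small-residue signal-peptidase site
    n_reg <- c("M", sample(c("K", "R", "A", "T", "Q"), n_len - 1L, replace = TRUE))
    h_reg <- sample(c("L", "I", "V", "F"), h_len, replace = TRUE)
    c_core <- sample(c("S", "T", "Q", "N", "A", "G"), c_len - 3L, replace = TRUE)
    c_site <- c(sample(c("A", "G", "S"), 1L),      # -3
                sample(c("Q", "N", "H", "Y"), 1L), # -2
                sample(c("A", "G", "S"), 1L))      # -1
    sp <- c(n_reg, h_reg, c_core, c_site)
    mature <- .random_mature(len - length(sp))
    list(seq = paste(c(sp, mature), collapse = ""),
         signal_len = length(sp))
  } else {
    # hydrophilic residues at every even position of the N-terminal 40
    # residues: no 8-residue window there reaches mean hydropathy 2.0,
    # so the planted protein is signal-peptide-negative by construction
    head_len <- min(40L, len)
    head <- sample(.AA20, head_len, replace = TRUE)
    head[1L] <- "M"
    even <- seq(2L, head_len, by = 2L)
    head[even] <- sample(c("D", "E", "N", "Q"), length(even), replace = TRUE)
    rest <- .random_mature(len - head_len)
    list(seq = paste(c(head, rest), collapse = ""), signal_len = NA_integer_)
  }
}

#' Generate a synthetic venom-gland transcriptome with ground truth
#'
#' Plants one ORF per contig (with untranslated flanks and random
#' strand), a secreted fraction carrying constructed signal peptides
#' that satisfy the secretome heuristic, venom flags, expression
#' levels (secreted proteins are more highly expressed, as in a
#' secretory tissue), keyword-bearing descriptions for venom contigs,
#' and GO annotations biased toward peptidase terms for venom contigs.
#'
#' @param config A [generator_config()].
#' @return A list: `contigs` ([Biostrings::DNAStringSet]),
#'   `annotations` (data.frame `contig_id`, `description`, `go_terms`),
#'   `truth` (one row per contig: ORF span/strand/frame, planted flags,
#'   planted protein sequence, expression level, qPCR fold change).
#' @export
generate_transcriptome <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    n <- config$n_contigs
    ids <- paste0("c", formatC(seq_len(n), width = max(4L, nchar(n)), flag = "0"))
    n_sec <- round(config$secreted_fraction * n)
    n_ven <- round(config$venom_fraction_of_secreted * n_sec)
    sec_idx <- sort(sample.int(n, n_sec))
    ven_idx <- sort(if (n_ven > 0L) sample(sec_idx, n_ven) else integer(0))
    is_secreted <- seq_len(n) %in% sec_idx
    is_venom <- seq_len(n) %in% ven_idx

    gc <- Biostrings::GENETIC_CODE
    syn <- split(names(gc), gc)
    stops <- syn[["*"]]

    len <- sample(config$protein_length_range[1L]:config$protein_length_range[2L],
                  n, replace = TRUE)
    u5 <- sample(config$utr_length_range[1L]:config$utr_length_range[2L],
                 n, replace = TRUE)
    u3 <- sample(config$utr_length_range[1L]:config$utr_length_range[2L],
                 n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    contigs <- character(n)
    protein <- character(n)
    signal_len <- integer(n)
    orf_start <- orf_end <- integer(n)
    frame <- character(n)
    for (i in seq_len(n)) {
      pr <- .random_protein(len[i], is_secreted[i])
      protein[i] <- pr$seq
      signal_len[i] <- pr$signal_len
      orf_nt <- paste0(.reverse_translate(pr$seq, syn),
                       stops[[sample.int(3L, 1L)]])
      utr5 <- paste(sample(c("A", "C", "G", "T"), u5[i], replace = TRUE),
                    collapse = "")
      # an in-frame stop immediately upstream keeps the planted ORF
      # 5'-complete (bounded by a stop, or abutting the contig start)
      if (u5[i] >= 3L)
        substr(utr5, u5[i] - 2L, u5[i]) <- stops[[sample.int(3L, 1L)]]
      utr3 <- paste(sample(c("A", "C", "G", "T"), u3[i], replace = TRUE),
                    collapse = "")
      sense <- paste0(utr5, orf_nt, utr3)
      tot <- nchar(sense)
      cds_len <- 3L * len[i]
      if (strand[i] == "+") {
        contigs[i] <- sense
        orf_start[i] <- u5[i]
        orf_end[i] <- u5[i] + cds_len
        frame[i] <- paste0("+", u5[i] %% 3L + 1L)
      } else {
        contigs[i] <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(sense)))
        orf_start[i] <- tot - (u5[i] + cds_len)
        orf_end[i] <- tot - u5[i]
        frame[i] <- paste0("-", u5[i] %% 3L + 1L)
      }
    }

    expression_level <- ifelse(is_secreted,
                               stats::rlnorm(n, log(300), 0.5),
                               stats::rlnorm(n, log(30), 1.0))

    fold <- rep(1, n)
    if (any(is_venom))
      fold[is_venom] <- exp(runif(sum(is_venom),
                                  log(config$qpcr_fold_change_range[1L]),
                                  log(config$qpcr_fold_change_range[2L])))

    description <- character(n)
    description[is_venom] <-
      sample(.VENOM_DESCRIPTIONS, sum(is_venom), replace = TRUE)
    sec_nv <- is_secreted & !is_venom
    description[sec_nv] <-
      sample(.SECRETED_NONVENOM_DESCRIPTIONS, sum(sec_nv), replace = TRUE)
    other <- !is_secreted
    description[other] <-
      sample(.HOUSE_DESCRIPTIONS, sum(other), replace = TRUE)
    nv <- which(!is_venom)
    n_unann <- round(config$unannotated_fraction * length(nv))
    if (n_unann > 0L) description[sample(nv, n_unann)] <- ""

    ont <- venom_mini_ontology()
    peptidase_terms <- c("GO:0004252", "GO:0008233", "GO:0004175")
    binding_terms <- c("GO:0005515", "GO:0003676", "GO:0043169", "GO:0005488")
    other_terms <- c("GO:0016787", "GO:0016740", "GO:0003824")
    go_terms <- character(n)
    for (i in seq_len(n)) {
      if (description[i] == "") { go_terms[i] <- ""; next }
      ts <- if (is_venom[i]) {
        sample(peptidase_terms, 1L + stats::rbinom(1L, 1L, 0.3),
               replace = FALSE)
      } else {
        sample(c(binding_terms, other_terms), sample(1:2, 1L))
      }
      go_terms[i] <- paste(sort(unique(ts)), collapse = "|")
    }

    contig_set <- Biostrings::DNAStringSet(setNames(contigs, ids))
    truth <- data.frame(
      contig_id = ids, orf_start = orf_start, orf_end = orf_end,
      strand = strand, frame = frame,
      is_secreted = is_secreted, is_venom = is_venom,
      homolog_identity = NA_real_,
      expression_level = expression_level,
      keyword_planted = is_venom,
      qpcr_fold_change = fold,
      protein = protein, signal_len = signal_len,
      stringsAsFactors = FALSE)
    annotations <- data.frame(contig_id = ids, description = description,
                              go_terms = go_terms, stringsAsFactors = FALSE)
    list(contigs = contig_set, annotations = annotations, truth = truth,
         ontology = ont, config = config)
  })
}

#' Generate the reference venom-protein set
#'
#' One reference entry per planted venom protein: the mature protein
#' (the signal peptide is removed, as reference venom sets describe the
#' secreted products), mutated by exact-count point substitutions to a
#' target identity drawn from the configured range, plus unrelated
#' decoy entries. The realised identity is written back into the
#' returned truth table.
#'
#' @param sim Output of [generate_transcriptome()].
#' @param config The same [generator_config()].
#' @return A list: `reference` ([Biostrings::AAStringSet], entries named
#'   `ref_<contig_id>` and `decoy_<k>`), `truth` (updated truth table
#'   with realised `homolog_identity`).
#' @export
generate_reference_venom_db <- function(sim, config = sim$config) {
  truth <- sim$truth
  .with_seed(config$seed + 1L, {
    ven <- which(truth$is_venom)
    seqs <- character(0)
    for (i in ven) {
      mature <- substr(truth$protein[i], truth$signal_len[i] + 1L,
                       nchar(truth$protein[i]))
      p <- strsplit(mature, "", fixed = TRUE)[[1L]]
      t_id <- runif(1L, config$homolog_identity_range[1L],
                    config$homolog_identity_range[2L])
      n_mut <- round((1 - t_id) * length(p))
      if (n_mut > 0L) {
        pos <- sample.int(length(p), n_mut)
        p[pos] <- vapply(p[pos], function(a)
          sample(setdiff(.AA20, a), 1L), "")
      }
      truth$homolog_identity[i] <- 1 - n_mut / length(p)
      seqs[paste0("ref_", truth$contig_id[i])] <- paste(p, collapse = "")
    }
    if (config$n_decoy_refs > 0L) {
      for (k in seq_len(config$n_decoy_refs)) {
        dl <- sample(config$protein_length_range[1L]:
                       config$protein_length_range[2L], 1L)
        seqs[sprintf("decoy_%02d", k)] <-
          paste(sample(.AA20, dl, replace = TRUE), collapse = "")
      }
    }
    list(reference = Biostrings::AAStringSet(seqs), truth = truth)
  })
}

#' Sample an observed tryptic-peptide list
#'
#' Draws peptides from the in-silico tryptic digests (up to 2 missed
#' cleavages, 7--35 residues, fully cleaved fragments favoured) of the
#' planted proteins, with per-protein counts Poisson-distributed around
#' `depth * expression / mean(expression)`, then appends
#' length-matched random contaminant peptides verified to match no
#' contig in any reading frame.
#'
#' @param sim Output of [generate_transcriptome()].
#' @param config The same [generator_config()].
#' @return A data.frame: `peptide`, `source_contig` (NA for
#'   contaminants), `is_contaminant`.
#' @export
sample_peptides <- function(sim, config = sim$config) {
  truth <- sim$truth
  .with_seed(config$seed + 2L, {
    params <- digestion_params(max_missed = 2L, min_len = 7L, max_len = 35L)
    rel <- truth$expression_level / mean(truth$expression_level)
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      lambda <- config$peptide_sampling_depth * rel[i]
      if (lambda <= 0) next
      k <- rpois(1L, lambda)
      if (k == 0L) next
      dig <- digest_protein(truth$protein[i], params)
      if (nrow(dig) == 0L) next
      w <- 0.6^dig$n_missed
      pick <- sample.int(nrow(dig), k, replace = TRUE, prob = w)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = dig$peptide[pick],
        source_contig = truth$contig_id[i],
        is_contaminant = FALSE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(peptide = character(), source_contig = character(),
                        is_contaminant = logical())
    rate <- config$contaminant_peptide_rate
    if (rate > 0 && nrow(out) > 0L) {
      n_cont <- round(rate / (1 - rate) * nrow(out))
      if (n_cont > 0L) {
        db_k <- chartr("I", "L", as.character(translate_contigs(sim$contigs)))
        cont <- character(0)
        while (length(cont) < n_cont) {
          pep <- paste(sample(.AA20, sample(7:25, 1L), replace = TRUE),
                       collapse = "")
          if (!any(grepl(chartr("I", "L", pep), db_k, fixed = TRUE)))
            cont <- c(cont, pep)
        }
        out <- rbind(out, data.frame(peptide = cont,
                                     source_contig = NA_character_,
                                     is_contaminant = TRUE,
                                     stringsAsFactors = FALSE))
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Simulate per-contig read counts
#'
#' Negative-binomial counts with mean `expression_level` and variance
#' `mu + phi mu^2`; `phi = 0` gives the deterministic rounded means.
#'
#' @param sim Output of [generate_transcriptome()].
#' @param config The same [generator_config()].
#' @return A data.frame `contig_id`, `length` (contig length in bases),
#'   `count`, with attribute `N` (library total) and `zero_library`
#'   flag.
#' @export
simulate_counts <- function(sim, config = sim$config) {
  truth <- sim$truth
  .with_seed(config$seed + 3L, {
    mu <- truth$expression_level
    phi <- config$count_dispersion
    count <- if (phi <= 0) as.integer(round(mu)) else
      rnbinom(length(mu), mu = mu, size = 1 / phi)
    out <- data.frame(contig_id = truth$contig_id,
                      length = Biostrings::width(sim$contigs),
                      count = count, stringsAsFactors = FALSE)
    attr(out, "N") <- sum(count)
    attr(out, "zero_library") <- sum(count) == 0L
    out
  })
}

#' Simulate a qPCR Ct table
#'
#' Target genes (venom contigs, with planted fold changes) and two
#' reference genes (fold change 1) are assayed in two groups
#' (venom_gland versus body) over three serial tenfold dilutions with
#' three biological x three technical replicates:
#' `Ct = intercept + S log10(dilution) - log(fold)/log(1 + E) + noise`,
#' where `S = -1/log10(1 + E)`.
#'
#' @param sim Output of [generate_transcriptome()].
#' @param config The same [generator_config()].
#' @return A data.frame `gene`, `group`, `dilution`, `bio_rep`,
#'   `tech_rep`, `ct`, with attribute `qpcr_truth` (per-gene efficiency
#'   and fold change).
#' @export
simulate_qpcr <- function(sim, config = sim$config) {
  truth <- sim$truth
  .with_seed(config$seed + 4L, {
    ven <- truth$contig_id[truth$is_venom]
    n_t <- min(config$n_qpcr_targets, length(ven))
    targets <- if (n_t > 0L) sort(sample(ven, n_t)) else character(0)
    genes <- c(targets, "GAPDH", "beta-tubulin")
    fold <- c(truth$qpcr_fold_change[match(targets, truth$contig_id)], 1, 1)
    E <- runif(length(genes), config$qpcr_efficiency_range[1L],
               config$qpcr_efficiency_range[2L])
    S <- -1 / log10(1 + E)
    intercept <- runif(length(genes), 18, 24)
    grid <- expand.grid(gene_i = seq_along(genes),
                        group = c("body", "venom_gland"),
                        dilution = c(1, 0.1, 0.01),
                        bio_rep = 1:3, tech_rep = 1:3,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    shift <- ifelse(grid$group == "venom_gland",
                    log(fold[grid$gene_i]) / log(1 + E[grid$gene_i]), 0)
    ct <- intercept[grid$gene_i] + S[grid$gene_i] * log10(grid$dilution) -
      shift + rnorm(nrow(grid), 0, config$qpcr_noise_sd)
    out <- data.frame(gene = genes[grid$gene_i], group = grid$group,
                      dilution = grid$dilution, bio_rep = grid$bio_rep,
                      tech_rep = grid$tech_rep, ct = ct,
                      stringsAsFactors = FALSE)
    attr(out, "qpcr_truth") <- data.frame(gene = genes, E = E, fold = fold,
                                          stringsAsFactors = FALSE)
    out
  })
}

#' Run all five generators at once
#'
#' @param config A [generator_config()].
#' @return A list: `contigs`, `annotations`, `truth` (with realised
#'   homolog identities), `ontology`, `reference`, `peptides`, `counts`,
#'   `qpcr`, `config`.
#' @export
simulate_venom_study <- function(config = generator_config()) {
  sim <- generate_transcriptome(config)
  ref <- generate_reference_venom_db(sim, config)
  sim$truth <- ref$truth
  sim$reference <- ref$reference
  sim$peptides <- sample_peptides(sim, config)
  sim$counts <- simulate_counts(sim, config)
  sim$qpcr <- simulate_qpcr(sim, config)
  sim
}

#' Write a simulated study to disk
#'
#' Emits the study as plain-text files: contigs and reference set as
#' FASTA, annotations / truth / peptides / counts as TSV, Ct values as
#' CSV.
#'
#' @param sim Output of [simulate_venom_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    contigs = file.path(dir, "contigs.fasta"),
    reference = file.path(dir, "reference_venom.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.tsv"),
    peptides = file.path(dir, "peptides.tsv"),
    counts = file.path(dir, "counts.tsv"),
    qpcr = file.path(dir, "qpcr.csv"))
  Biostrings::writeXStringSet(sim$contigs, paths[["contigs"]])
  Biostrings::writeXStringSet(sim$reference, paths[["reference"]])
  tsv <- function(x, p) write.table(x, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(sim$annotations, paths[["annotations"]])
  tsv(sim$truth, paths[["truth"]])
  tsv(sim$peptides, paths[["peptides"]])
  tsv(sim$counts, paths[["counts"]])
  write.csv(sim$qpcr, paths[["qpcr"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
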