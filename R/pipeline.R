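#' Run the integrated venom-protein identification pipeline
#'
#' Orchestrates the full analysis on one contig set: six-frame
#' translation, peptide mapping and candidate inference, secretome
#' filtering, homology search against the reference venom set,
#' annotation keyword mining with its signal-peptide breakdown,
#' optional RPKM quantification and GO enrichment, and the verified
#' count ledger.
#'
#' The secretory proteins unmatched by the reference set are
#' partitioned by annotation: descriptions carrying a venom/toxin
#' keyword count as "similar to other venom components", empty
#' descriptions as unannotated, and the rest as venom trace elements.
#' The proteomic venom set is the reference-matched plus
#' other-venom-similar contigs; keyword-only transcripts (keyword hits
#' not already in that set) are added to form the total venom set.
#'
#' @param contigs Named [Biostrings::DNAStringSet] or character vector.
#' @param annotations data.frame `contig_id`, `description`, optional
#'   `go_terms`.
#' @param peptides Character vector of observed peptides (or data.frame
#'   with a `peptide` column).
#' @param reference Named [Biostrings::AAStringSet] or character vector
#'   of reference venom proteins.
#' @param counts Optional count table (`contig_id`, `length`, `count`).
#' @param ontology Optional `ontology` object for GO enrichment of the
#'   venom set against the whole transcriptome.
#' @param keywords Annotation keywords (default `c("venom", "toxin")`).
#' @param il_equivalence,min_peptides,require_tryptic Peptide mapping
#'   and aggregation settings.
#' @param external_sp_calls Optional external signal-peptide table (see
#'   [import_external_sp_calls()]).
#' @param min_identity,min_coverage,min_score Homology thresholds.
#' @param alpha Enrichment FDR threshold.
#' @return A list of class `venom_analysis`: the stage tables
#'   (`db`, `matches`, `candidates`, `sp_calls`, `secretome`,
#'   `homology`, `keyword_ids`, `keyword_breakdown`, `expression`,
#'   `enrichment`), the contig-level sets (`sets`), the verified
#'   `ledger` and the category assignment (`categories`).
#' @export
run_venom_pipeline <- function(contigs, annotations, peptides, reference,
                               counts = NULL, ontology = NULL,
                               keywords = c("venom", "toxin"),
                               il_equivalence = TRUE, min_peptides = 1L,
                               require_tryptic = FALSE,
                               external_sp_calls = NULL,
                               min_identity = 35, min_coverage = 0.5,
                               min_score = 50, alpha = 0.05) {
  if (is.data.frame(peptides)) peptides <- peptides$peptide
  db <- translate_contigs(contigs)
  matches <- map_peptides(peptides, db, il_equivalence = il_equivalence)
  candidates <- infer_identified_contigs(matches, db,
                                         min_peptides = min_peptides,
                                         require_tryptic = require_tryptic)
  sp_calls <- if (is.null(external_sp_calls))
    signal_peptide_calls(candidates)
  else import_external_sp_calls(external_sp_calls, candidates)
  secretome <- filter_secretome(candidates, sp_calls)

  queries <- setNames(secretome$orf_seq, secretome$protein_id)
  homology <- if (length(queries) > 0L)
    search_reference(queries, reference, min_identity = min_identity,
                     min_coverage = min_coverage, min_score = min_score)
  else search_reference(character(0), as.character(reference))

  desc_of <- function(ids)
    annotations$description[match(ids, annotations$contig_id)]

  sec_contigs <- unique(secretome$contig_id)
  matched_pids <- unique(homology$query_id)
  ref_matched <- unique(secretome$contig_id[secretome$protein_id %in% matched_pids])
  unmatched <- setdiff(sec_contigs, ref_matched)
  d <- desc_of(unmatched)
  has_kw <- rep(FALSE, length(unmatched))
  for (k in tolower(keywords))
    has_kw <- has_kw | grepl(k, tolower(ifelse(is.na(d), "", d)), fixed = TRUE)
  unannotated <- unmatched[is.na(d) | !nzchar(d)]
  other_similar <- setdiff(unmatched[has_kw], unannotated)
  trace <- setdiff(unmatched, c(other_similar, unannotated))
  venom_proteomic <- union(ref_matched, other_similar)
  if (length(intersect(venom_proteomic, trace)) > 0L)
    stop("a protein is classified both venom and trace")

  # keyword mining over the whole transcriptome
  keyword_ids <- select_by_keyword(annotations, keywords)
  kw_break <- .keyword_breakdown_for(keyword_ids, db, candidates, sp_calls)
  keyword_only <- setdiff(keyword_ids, venom_proteomic)
  venom_total <- union(venom_proteomic, keyword_only)

  expression <- NULL
  top_venom <- NULL
  if (!is.null(counts)) {
    expression <- rpkm_table(counts)
    ranked <- rank_by_expression(expression, annotations)
    top_venom <- ranked[ranked$contig_id %in% venom_total, , drop = FALSE]
    rownames(top_venom) <- NULL
  }

  enrichment <- NULL
  if (!is.null(ontology) && "go_terms" %in% names(annotations)) {
    ann <- annotations[!is.na(annotations$go_terms) &
                         nzchar(annotations$go_terms), , drop = FALSE]
    test <- intersect(venom_total, ann$contig_id)
    if (length(test) > 0L)
      enrichment <- enrich_terms(test, ann$contig_id, ann, ontology,
                                 alpha = alpha)
  }

  ledger <- build_ledger(
    n_contigs = length(contigs),
    n_peptides_observed = length(unique(peptides[nzchar(peptides)])),
    n_identified_contigs = length(unique(candidates$contig_id)),
    n_secretory = length(sec_contigs),
    n_ref_matched = length(ref_matched),
    n_other_venom_similar = length(other_similar),
    n_unannotated = length(unannotated),
    n_trace_elements = length(trace),
    n_keyword_total = length(keyword_ids),
    n_keyword_sp = kw_break$n_with_sp,
    n_keyword_incomplete_5prime = kw_break$n_incomplete_5prime,
    n_keyword_complete = kw_break$n_complete,
    n_keyword_too_small = kw_break$n_too_small,
    n_keyword_only = length(keyword_only))

  categories <- categorize_proteins(venom_total, desc_of(venom_total))

  structure(list(
    db = db, matches = matches, candidates = candidates,
    sp_calls = sp_calls, secretome = secretome, homology = homology,
    keyword_ids = keyword_ids, keyword_breakdown = kw_break,
    expression = expression, top_venom = top_venom,
    enrichment = enrichment,
    sets = list(identified = unique(candidates$contig_id),
                secretory = sec_contigs,
                ref_matched = ref_matched,
                other_venom_similar = other_similar,
                unannotated = unannotated,
                trace = trace,
                venom_proteomic = venom_proteomic,
                keyword = as.character(keyword_ids),
                keyword_only = keyword_only,
                venom_total = venom_total),
    ledger = ledger, categories = categories), class = "venom_analysis")
}

# signal-peptide / completeness breakdown of the keyword set: use the
# proteomic candidate's call when the contig was identified, otherwise
# evaluate the contig's longest ORF across the six frames
.keyword_breakdown_for <- function(keyword_ids, db, candidates, sp_calls) {
  keyword_ids <- as.character(keyword_ids)
  if (length(keyword_ids) == 0L)
    return(build_keyword_breakdown(character(0), character(0),
                                   setNames(character(0), character(0))))
  sp_pos <- character(0)
  completeness <- setNames(rep(NA_character_, length(keyword_ids)), keyword_ids)
  pos_pids <- sp_calls$protein_id[!is.na(sp_calls$is_secreted) &
                                    sp_calls$is_secreted]
  cand_by_contig <- split(candidates, candidates$contig_id)
  dbn <- parse_protein_id(names(db))
  for (cid in keyword_ids) {
    cand <- cand_by_contig[[cid]]
    if (!is.null(cand) && any(cand$protein_id %in% pos_pids)) {
      sp_pos <- c(sp_pos, cid)
      next
    }
    if (!is.null(cand) && !all(is.na(cand$completeness))) {
      cc <- cand$completeness[!is.na(cand$completeness)]
      completeness[[cid]] <- cc[[1L]]
      next
    }
    # not identified proteomically: best ORF over the six frames
    orfs <- orf_table(db[which(dbn$contig_id == cid)])
    if (nrow(orfs) == 0L) { completeness[[cid]] <- "too_small"; next }
    len <- orfs$aa_end - orfs$aa_start
    best <- orfs[order(-len)[1L], , drop = FALSE]
    call <- score_signal_peptide(best$orf_seq, best$completeness)
    if (isTRUE(call$is_secreted)) sp_pos <- c(sp_pos, cid)
    else completeness[[cid]] <- best$completeness
  }
  build_keyword_breakdown(keyword_ids, sp_pos, completeness)
}

#' @export
print.venom_analysis <- function(x, ...) {
  cat("Integrated venom protein analysis\n")
  print(x$ledger)
  invisible(x)
}

#' Compare pipeline output against planted truth
#'
#' Sensitivity and false-discovery proportion of the recovered venom
#' set (proteomic by default) against the generator's planted venom
#' flags.
#'
#' @param result A `venom_analysis`.
#' @param truth A generator truth table.
#' @param set Which recovered set to score (default
#'   `"venom_proteomic"`).
#' @return A list: `sensitivity`, `fdp`, `tp`, `fp`, `fn`.
#' @export
evaluate_recovery <- function(result, truth, set = "venom_proteomic") {
  predicted <- result$sets[[set]]
  planted <- truth$contig_id[truth$is_venom]
  tp <- length(intersect(predicted, planted))
  fp <- length(setdiff(predicted, planted))
  fn <- length(setdiff(planted, predicted))
  list(sensitivity = if (length(planted) > 0L) tp / length(planted) else NA,
       fdp = if (length(predicted) > 0L) fp / length(predicted) else 0,
       tp = tp, fp = fp, fn = fn)
}
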