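#' Assemble and verify the venom count ledger
#'
#' Takes the primitive stage counts and derives the remaining
#' quantities, enforcing the arithmetic identities that link the sets:
#'
#' * `n_db_entries = 6 * n_contigs`
#' * `n_ref_unmatched = n_secretory - n_ref_matched`
#' * `n_ref_unmatched = n_other_venom_similar + n_unannotated + n_trace_elements`
#' * `n_venom_proteomic = n_ref_matched + n_other_venom_similar`
#' * `n_venom_total = n_venom_proteomic + n_keyword_only`
#' * `n_keyword_total = n_keyword_sp + n_keyword_missing_sp`, with
#'   `n_keyword_missing_sp` split into 5'-incomplete, complete and
#'   too-small
#'
#' Any violated identity is a hard error naming the identity.
#'
#' @param n_contigs Contigs in the assembly.
#' @param n_peptides_observed Observed peptide sequences.
#' @param n_identified_contigs Contigs with peptide evidence.
#' @param n_secretory Identified proteins bearing a signal peptide.
#' @param n_ref_matched Secretory proteins matching the reference venom
#'   set.
#' @param n_other_venom_similar Secretory proteins unmatched by the
#'   reference set but similar to other venom components.
#' @param n_unannotated Secretory proteins with no annotation at all.
#' @param n_trace_elements Secretory proteins with no venom similarity
#'   (venom trace elements / dissection contaminants).
#' @param n_keyword_total Contigs selected by annotation keyword.
#' @param n_keyword_sp Keyword contigs with a signal peptide.
#' @param n_keyword_incomplete_5prime,n_keyword_complete,n_keyword_too_small
#'   Split of the keyword contigs missing the signal peptide.
#' @param n_keyword_only Keyword contigs not already in the proteomic
#'   venom set (defaults to `n_keyword_total`, i.e. a disjoint keyword
#'   set).
#' @return A list of class `venom_ledger` with all primitive and
#'   derived counts.
#' @export
build_ledger <- function(n_contigs,
                         n_peptides_observed,
                         n_identified_contigs,
                         n_secretory,
                         n_ref_matched,
                         n_other_venom_similar,
                         n_unannotated,
                         n_trace_elements,
                         n_keyword_total,
                         n_keyword_sp,
                         n_keyword_incomplete_5prime,
                         n_keyword_complete,
                         n_keyword_too_small,
                         n_keyword_only = n_keyword_total) {
  counts <- c(n_contigs, n_peptides_observed, n_identified_contigs,
              n_secretory, n_ref_matched, n_other_venom_similar,
              n_unannotated, n_trace_elements, n_keyword_total,
              n_keyword_sp, n_keyword_incomplete_5prime,
              n_keyword_complete, n_keyword_too_small, n_keyword_only)
  if (any(is.na(counts)) || any(counts < 0))
    stop("all ledger counts must be non-negative")

  n_db_entries <- 6L * n_contigs
  n_ref_unmatched <- n_secretory - n_ref_matched
  if (n_ref_unmatched < 0)
    stop("ledger identity violated: n_secretory = n_ref_matched + n_ref_unmatched")
  if (n_ref_unmatched !=
      n_other_venom_similar + n_unannotated + n_trace_elements)
    stop("ledger identity violated: n_ref_unmatched = ",
         "n_other_venom_similar + n_unannotated + n_trace_elements")
  n_venom_proteomic <- n_ref_matched + n_other_venom_similar
  n_keyword_missing_sp <- n_keyword_total - n_keyword_sp
  if (n_keyword_missing_sp < 0)
    stop("ledger identity violated: n_keyword_total = ",
         "n_keyword_sp + n_keyword_missing_sp")
  if (n_keyword_missing_sp !=
      n_keyword_incomplete_5prime + n_keyword_complete + n_keyword_too_small)
    stop("ledger identity violated: n_keyword_missing_sp = ",
         "n_keyword_incomplete_5prime + n_keyword_complete + n_keyword_too_small")
  n_venom_total <- n_venom_proteomic + n_keyword_only

  structure(list(
    n_contigs = n_contigs,
    n_db_entries = n_db_entries,
    n_peptides_observed = n_peptides_observed,
    n_identified_contigs = n_identified_contigs,
    n_secretory = n_secretory,
    n_ref_matched = n_ref_matched,
    n_ref_unmatched = n_ref_unmatched,
    n_other_venom_similar = n_other_venom_similar,
    n_unannotated = n_unannotated,
    n_trace_elements = n_trace_elements,
    n_venom_proteomic = n_venom_proteomic,
    n_keyword_total = n_keyword_total,
    n_keyword_sp = n_keyword_sp,
    n_keyword_missing_sp = n_keyword_missing_sp,
    n_keyword_incomplete_5prime = n_keyword_incomplete_5prime,
    n_keyword_complete = n_keyword_complete,
    n_keyword_too_small = n_keyword_too_small,
    n_keyword_only = n_keyword_only,
    n_venom_total = n_venom_total), class = "venom_ledger")
}

#' @export
print.venom_ledger <- function(x, ...) {
  cat("Venom count ledger\n")
  for (nm in names(x)) cat(sprintf("  %-28s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Category rules for venom-protein annotation descriptions
#'
#' An editable pattern file mapping description regexes
#' (case-insensitive, first match wins) to functional categories
#' (hydrolase subfamilies, protease inhibitors, immune-related,
#' recognition/binding, and so on). Descriptions matching no rule fall
#' into "Unknown and hypothetical proteins".
#'
#' @param path Optional path to a custom rules TSV (`pattern`,
#'   `category`, `subcategory`); defaults to the bundled rules.
#' @return A data.frame of rules.
#' @export
venom_category_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "category_rules.tsv", package = "venomics")
  rules <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pattern", "category", "subcategory")
  if (!all(need %in% names(rules)))
    stop("rule file must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(rules$pattern) | !nzchar(rules$pattern))
  if (length(bad) > 0L) stop("malformed rule at index ", bad[[1L]])
  rules
}

#' Assign each venom protein to a functional category
#'
#' First-matching-rule assignment of annotation descriptions to the
#' functional category table; unmatched or empty descriptions are
#' "Unknown and hypothetical proteins". Total and deterministic.
#'
#' @param ids Contig or protein ids.
#' @param descriptions Matching annotation descriptions.
#' @param rules Rules data.frame from [venom_category_rules()].
#' @return A data.frame: `id`, `category`, `subcategory`, `evidence`
#'   (the matched pattern, NA for the default).
#' @export
categorize_proteins <- function(ids, descriptions,
                                rules = venom_category_rules()) {
  stopifnot(length(ids) == length(descriptions))
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch(suppressWarnings(
      grepl(rules$pattern[i], "", perl = TRUE, ignore.case = TRUE)),
      error = function(e) NA)
    if (is.na(ok)) stop("malformed rule at index ", i, ": ", rules$pattern[i])
  }
  desc <- ifelse(is.na(descriptions), "", descriptions)
  cat_i <- rep(NA_integer_, length(ids))
  for (i in seq_len(nrow(rules))) {
    hit <- is.na(cat_i) & grepl(rules$pattern[i], desc, perl = TRUE,
                                ignore.case = TRUE)
    cat_i[hit] <- i
  }
  data.frame(
    id = ids,
    category = ifelse(is.na(cat_i), "Unknown and hypothetical proteins",
                      rules$category[cat_i]),
    subcategory = ifelse(is.na(cat_i), "Uncharacterized proteins",
                         rules$subcategory[cat_i]),
    evidence = ifelse(is.na(cat_i), NA_character_, rules$pattern[cat_i]),
    stringsAsFactors = FALSE)
}

#' Export the ledger, categories and expression ranking
#'
#' Writes a machine-readable JSON summary, the ledger and category
#' tables as TSV, and a short human-readable text report. Re-running on
#' identical inputs produces byte-identical files.
#'
#' @param ledger A `venom_ledger`.
#' @param categories Output of [categorize_proteins()] (optional).
#' @param rankings Output of [rank_by_expression()] (optional).
#' @param dir Output directory.
#' @return Invisibly, the written file paths.
#' @export
export_report <- function(ledger, categories = NULL, rankings = NULL, dir) {
  stopifnot(inherits(ledger, "venom_ledger"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(dir, "ledger.json"),
             ledger = file.path(dir, "ledger.tsv"),
             report = file.path(dir, "report.txt"))
  jsonlite::write_json(unclass(ledger), paths[["json"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write.table(data.frame(count = names(ledger),
                         value = unlist(ledger, use.names = FALSE)),
              paths[["ledger"]], sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c("Venom protein identification summary",
             sprintf("  contigs: %d (database entries: %d)",
                     ledger$n_contigs, ledger$n_db_entries),
             sprintf("  peptides observed: %d -> identified contigs: %d",
                     ledger$n_peptides_observed, ledger$n_identified_contigs),
             sprintf("  secretory proteins: %d (reference-matched %d, other venom-similar %d, unannotated %d, trace %d)",
                     ledger$n_secretory, ledger$n_ref_matched,
                     ledger$n_other_venom_similar, ledger$n_unannotated,
                     ledger$n_trace_elements),
             sprintf("  proteomic venom proteins: %d", ledger$n_venom_proteomic),
             sprintf("  keyword transcripts: %d (with SP %d, missing SP %d), keyword-only %d",
                     ledger$n_keyword_total, ledger$n_keyword_sp,
                     ledger$n_keyword_missing_sp, ledger$n_keyword_only),
             sprintf("  total venom proteins: %d", ledger$n_venom_total))
  if (!is.null(categories)) {
    paths[["categories"]] <- file.path(dir, "categories.tsv")
    write.table(categories, paths[["categories"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    tab <- sort(table(categories$category), decreasing = TRUE)
    lines <- c(lines, "  categories:",
               sprintf("    %s: %d", names(tab), as.integer(tab)))
  }
  if (!is.null(rankings)) {
    paths[["rankings"]] <- file.path(dir, "top_expressed.tsv")
    write.table(rankings, paths[["rankings"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  writeLines(lines, paths[["report"]])
  invisible(paths)
}
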