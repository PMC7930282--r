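#' Select contigs by annotation keyword
#'
#' Case-insensitive substring search of each keyword in the annotation
#' descriptions. Substring (not word-boundary) semantics are deliberate:
#' venom nomenclature includes compounds such as "plancitoxin" that a
#' word-boundary match would miss; the per-keyword report surfaces any
#' resulting false positives.
#'
#' @param annotations A data.frame with columns `contig_id` and
#'   `description` (`contig_id` unique).
#' @param keywords Non-empty character vector (default
#'   `c("venom", "toxin")`).
#' @return Character vector of selected contig ids (union over
#'   keywords), with attribute `per_keyword`: a named list of the ids
#'   selected by each keyword.
#' @export
select_by_keyword <- function(annotations, keywords = c("venom", "toxin")) {
  stopifnot(is.data.frame(annotations),
            all(c("contig_id", "description") %in% names(annotations)))
  if (length(keywords) == 0L) stop("keywords must be non-empty")
  if (anyDuplicated(annotations$contig_id))
    stop("contig_id must be unique in the annotation table")
  desc <- tolower(ifelse(is.na(annotations$description), "",
                         annotations$description))
  per <- lapply(tolower(keywords), function(k)
    annotations$contig_id[grepl(k, desc, fixed = TRUE)])
  names(per) <- keywords
  out <- unique(unlist(per, use.names = FALSE))
  if (is.null(out)) out <- character(0)
  attr(out, "per_keyword") <- per
  out
}

#' Signal-peptide / completeness breakdown of the keyword set
#'
#' For the keyword-selected contigs, counts how many bear a signal
#' peptide and splits the remainder by ORF 5'-completeness. Contigs with
#' a positive signal-peptide call are counted as bearing the signature
#' regardless of completeness. Both additivity identities
#' (`n_keyword = n_with_sp + n_missing_sp` and
#' `n_missing_sp = n_incomplete_5prime + n_complete + n_too_small`) are
#' checked, not assumed.
#'
#' @param keyword_ids Contig ids from [select_by_keyword()].
#' @param sp_positive Contig ids with a positive signal-peptide call.
#' @param completeness Named character vector: completeness label per
#'   contig (names are contig ids); required for every keyword contig
#'   without a positive call.
#' @return A list of class `keyword_breakdown` with the six counts.
#' @export
build_keyword_breakdown <- function(keyword_ids, sp_positive, completeness) {
  keyword_ids <- unique(as.character(keyword_ids))
  with_sp <- keyword_ids %in% sp_positive
  missing_ids <- keyword_ids[!with_sp]
  lab <- completeness[missing_ids]
  if (any(is.na(lab) | is.null(lab)) && length(missing_ids) > 0L) {
    bad <- missing_ids[is.na(lab)]
    if (length(bad) > 0L)
      stop("keyword contig lacks both a signal-peptide call and a ",
           "completeness label: ", bad[[1L]])
  }
  # a 'no_start' ORF carries no evaluable N-terminus: counted as 5'-incomplete
  lab[lab == "no_start"] <- "incomplete_5prime"
  out <- list(
    n_keyword = length(keyword_ids),
    n_with_sp = sum(with_sp),
    n_missing_sp = length(missing_ids),
    n_incomplete_5prime = sum(lab == "incomplete_5prime"),
    n_complete = sum(lab == "complete"),
    n_too_small = sum(lab == "too_small")
  )
  if (out$n_keyword != out$n_with_sp + out$n_missing_sp)
    stop("keyword breakdown identity violated: n_keyword")
  if (out$n_missing_sp !=
      out$n_incomplete_5prime + out$n_complete + out$n_too_small)
    stop("keyword breakdown identity violated: n_missing_sp split")
  structure(out, class = "keyword_breakdown")
}
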