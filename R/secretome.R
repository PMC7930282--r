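#' Kyte-Doolittle hydropathy scale
#' @return Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

# residues tolerated at the -3/-1 positions of a signal-peptidase site
.SP_SMALL <- c("A", "G", "S", "C", "T", "V")
.SP_H_WINDOW <- 8L
.SP_H_MIN <- 2.0
.SP_SITE_RANGE <- c(15L, 35L)

#' Score an N-terminal signal peptide
#'
#' A transparent von-Heijne-style heuristic standing in for a trained
#' signal-peptide predictor: a sequence is called secreted when some
#' cleavage site p in 15..35 satisfies (a) small residues (A,G,S,C,T,V)
#' at the -3 and -1 positions relative to the site, (b) an 8-residue
#' window within positions 1..p whose mean Kyte-Doolittle hydropathy is
#' >= 2.0 (the hydrophobic h-region), and (c) a non-negative net charge
#' (K,R: +1; D,E: -1) over the n-region preceding that window. Among
#' valid sites, the one whose best h-window has the highest hydropathy
#' wins, ties broken toward the smallest p.
#'
#' The heuristic assumes the sequence starts at the true N-terminus;
#' candidates from 5'-incomplete ORFs should be given
#' `completeness = "incomplete_5prime"` and receive a no-call rather than
#' a negative call. Genuine external predictions can be substituted via
#' [import_external_sp_calls()].
#'
#' @param aa_seq A single amino-acid sequence beginning at the initiator
#'   methionine.
#' @param completeness Optional ORF completeness label; anything other
#'   than `"complete"` yields a no-call.
#' @return A one-row data.frame: `is_secreted`, `cleavage_site` (1-based
#'   residue after which cleavage occurs; NA if negative), `score` (mean
#'   hydropathy of the best h-window; NA if no window), `no_call_reason`
#'   (NA, `"too_short"` or `"incomplete_5prime"`).
#' @export
score_signal_peptide <- function(aa_seq, completeness = "complete") {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  no_call <- function(reason) data.frame(
    is_secreted = NA, cleavage_site = NA_integer_, score = NA_real_,
    no_call_reason = reason, stringsAsFactors = FALSE)
  negative <- function(score) data.frame(
    is_secreted = FALSE, cleavage_site = NA_integer_, score = score,
    no_call_reason = NA_character_, stringsAsFactors = FALSE)
  if (!identical(completeness, "complete")) {
    if (identical(completeness, "too_small")) return(no_call("too_short"))
    return(no_call("incomplete_5prime"))
  }
  if (nchar(aa_seq) < 18L) return(no_call("too_short"))

  kd <- kyte_doolittle()
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  pmax_ <- min(.SP_SITE_RANGE[2L], length(res))
  hyd <- unname(kd[res])
  hyd[is.na(hyd)] <- 0  # X or other non-standard letters are neutral
  charge <- ifelse(res %in% c("K", "R"), 1L, ifelse(res %in% c("D", "E"), -1L, 0L))
  cum_charge <- cumsum(charge)
  # mean hydropathy of every 8-residue window starting at w (1-based)
  nw <- length(res) - .SP_H_WINDOW + 1L
  if (nw < 1L) return(negative(NA_real_))
  win_mean <- (cumsum(hyd)[.SP_H_WINDOW:length(res)] -
                 c(0, cumsum(hyd))[1:nw]) / .SP_H_WINDOW

  best_p <- NA_integer_; best_h <- -Inf
  for (p in .SP_SITE_RANGE[1L]:pmax_) {
    if (!(res[p] %in% .SP_SMALL) || !(res[p - 2L] %in% .SP_SMALL)) next
    w_last <- p - .SP_H_WINDOW + 1L  # last window start fully within 1..p
    if (w_last < 1L) next
    ok <- which(win_mean[seq_len(min(w_last, nw))] >= .SP_H_MIN)
    # n-region charge: positions 1..(window start - 1)
    ok <- ok[c(0L, cum_charge)[ok] >= 0L]
    if (length(ok) == 0L) next
    h <- max(win_mean[ok])
    if (h > best_h) { best_h <- h; best_p <- p }  # ties: smallest p kept
  }
  if (is.na(best_p)) {
    sc <- if (nw >= 1L) max(win_mean[seq_len(min(nw, pmax_))]) else NA_real_
    return(negative(sc))
  }
  data.frame(is_secreted = TRUE, cleavage_site = best_p, score = best_h,
             no_call_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Signal-peptide calls for a candidate table
#'
#' Applies [score_signal_peptide()] to each candidate's ORF sequence,
#' honouring the completeness label (5'-incomplete and too-small ORFs
#' receive no-calls).
#'
#' @param candidates Output of [infer_identified_contigs()], or any
#'   data.frame with `protein_id`, `orf_seq` and `completeness` columns.
#' @return A data.frame keyed by `protein_id` with the call columns of
#'   [score_signal_peptide()] plus `provenance = "heuristic"`.
#' @export
signal_peptide_calls <- function(candidates) {
  stopifnot(all(c("protein_id", "orf_seq", "completeness") %in% names(candidates)))
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    compl <- candidates$completeness[[i]]
    seq_i <- candidates$orf_seq[[i]]
    if (is.na(compl) || is.na(seq_i)) compl <- "incomplete_5prime"
    call <- score_signal_peptide(if (is.na(seq_i)) "" else seq_i, compl)
    call$protein_id <- candidates$protein_id[[i]]
    call
  })
  out <- do.call(rbind, rows)
  out$provenance <- "heuristic"
  out[, c("protein_id", "is_secreted", "cleavage_site", "score",
          "no_call_reason", "provenance")]
}

#' Filter candidates to the secretome
#'
#' Keeps exactly the candidates with a positive signal-peptide call.
#' No-call candidates are excluded and counted separately (attribute
#' `n_no_call`, split by reason in attribute `no_call_reasons`).
#'
#' @param candidates Candidate data.frame with a `protein_id` column.
#' @param calls Calls from [signal_peptide_calls()] or
#'   [import_external_sp_calls()]; one per candidate.
#' @return The retained subset of `candidates`.
#' @export
filter_secretome <- function(candidates, calls) {
  missing <- setdiff(candidates$protein_id, calls$protein_id)
  if (length(missing) > 0L)
    stop("candidate without a signal-peptide call: ", missing[[1L]])
  calls <- calls[match(candidates$protein_id, calls$protein_id), , drop = FALSE]
  no_call <- is.na(calls$is_secreted)
  keep <- !no_call & calls$is_secreted
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_no_call") <- sum(no_call)
  attr(out, "no_call_reasons") <- table(calls$no_call_reason[no_call])
  out
}

#' Import external signal-peptide predictions
#'
#' Lets users substitute genuine predictor output (e.g. SignalP) for the
#' built-in heuristic. The table must have columns `protein_id`, a
#' yes/no flag (`YES`/`NO`, `TRUE`/`FALSE`, `1`/`0`, case-insensitive)
#' and an optional cleavage site.
#'
#' @param table A data.frame or path to a TSV with columns
#'   `protein_id`, `is_secreted`, `cleavage_site`.
#' @param candidates Candidate table whose `protein_id`s the calls must
#'   refer to.
#' @return A calls data.frame as from [signal_peptide_calls()], with
#'   `provenance = "external"`.
#' @export
import_external_sp_calls <- function(table, candidates) {
  if (is.character(table)) {
    table <- read.delim(table, stringsAsFactors = FALSE)
  }
  need <- c("protein_id", "is_secreted")
  if (!all(need %in% names(table)))
    stop("external call table must have columns: ", paste(need, collapse = ", "))
  unknown <- setdiff(table$protein_id, candidates$protein_id)
  if (length(unknown) > 0L)
    stop("external call names unknown protein id: ", unknown[[1L]])
  flag_raw <- toupper(trimws(as.character(table$is_secreted)))
  flag <- flag_raw %in% c("YES", "Y", "TRUE", "T", "1")
  bad <- !flag & !flag_raw %in% c("NO", "N", "FALSE", "F", "0")
  if (any(bad))
    stop("malformed external call at row ", which(bad)[[1L]],
         ": flag '", table$is_secreted[bad][[1L]], "'")
  site <- if ("cleavage_site" %in% names(table))
    suppressWarnings(as.integer(table$cleavage_site)) else NA_integer_
  data.frame(protein_id = table$protein_id,
             is_secreted = flag,
             cleavage_site = ifelse(flag, site, NA_integer_),
             score = NA_real_,
             no_call_reason = NA_character_,
             provenance = "external",
             stringsAsFactors = FALSE)
}
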