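#' BLOSUM62 substitution matrix with neutral X
#'
#' The conventional BLOSUM62 matrix restricted to the 20 standard amino
#' acids plus X, with X scoring 0 against every letter (an ambiguous
#' residue neither rewards nor penalises alignment).
#'
#' @return A 21 x 21 numeric matrix with dimnames.
#' @export
venom_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  m <- m[aa, aa]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

.encode_aa <- function(seq, alphabet) {
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(res, alphabet)
  idx[is.na(idx)] <- match("X", alphabet)  # unknown letters behave as X
  idx - 1L
}

#' Pairwise alignment with affine gaps
#'
#' Exact optimal alignment by dynamic programming: local
#' (Smith-Waterman) or global (Needleman-Wunsch), with affine gap costs
#' (a gap of length k costs `gap_open + (k - 1) * gap_extend`).
#' Traceback ties are broken toward the diagonal, then up, so the
#' reported alignment is deterministic.
#'
#' @param a,b Amino-acid sequences (single character strings).
#' @param type `"local"` or `"global"`.
#' @param matrix Substitution matrix with dimnames; default
#'   [venom_blosum62()].
#' @param gap_open,gap_extend Gap penalties (positive numbers; defaults
#'   11 and 1, the conventional BLOSUM62 pairing).
#' @return A list: `score`, `aligned_a`, `aligned_b` (gapped strings),
#'   `a_span`/`b_span` (0-based half-open aligned intervals),
#'   `identity` (fraction of identical alignment columns),
#'   `query_coverage` (aligned fraction of `a`), `n_columns`.
#' @examples
#' align_pair("PAWHEAE", "PAWHEAE")$score
#' @export
align_pair <- function(a, b, type = c("local", "global"),
                       matrix = venom_blosum62(),
                       gap_open = 11, gap_extend = 1) {
  type <- match.arg(type)
  stopifnot(is.character(a), is.character(b), length(a) == 1L,
            length(b) == 1L, gap_open >= 0, gap_extend >= 0)
  alphabet <- rownames(matrix)
  ai <- .encode_aa(a, alphabet)
  bi <- .encode_aa(b, alphabet)
  r <- align_affine_cpp(ai, bi, matrix, gap_open, gap_extend,
                        if (type == "local") 0L else 1L)
  ops <- strsplit(r$ops, "", fixed = TRUE)[[1L]]
  n_cols <- length(ops)
  if (n_cols == 0L) {
    return(list(score = r$score, aligned_a = "", aligned_b = "",
                a_span = c(0L, 0L), b_span = c(0L, 0L),
                identity = NA_real_, query_coverage = 0, n_columns = 0L))
  }
  a_res <- strsplit(a, "", fixed = TRUE)[[1L]]
  b_res <- strsplit(b, "", fixed = TRUE)[[1L]]
  ca <- cb <- character(n_cols)
  ia <- r$a_start; ib <- r$b_start
  for (k in seq_len(n_cols)) {
    if (ops[k] != "I") { ca[k] <- a_res[ia]; ia <- ia + 1L } else ca[k] <- "-"
    if (ops[k] != "D") { cb[k] <- b_res[ib]; ib <- ib + 1L } else cb[k] <- "-"
  }
  n_id <- sum(ca == cb & ca != "-")
  list(score = r$score,
       aligned_a = paste(ca, collapse = ""),
       aligned_b = paste(cb, collapse = ""),
       a_span = c(r$a_start - 1L, r$a_end),
       b_span = c(r$b_start - 1L, r$b_end),
       identity = n_id / n_cols,
       query_coverage = sum(ops != "I") / nchar(a),
       n_columns = n_cols)
}

#' Optimal local alignment (Smith-Waterman)
#'
#' Convenience wrapper around [align_pair()] with `type = "local"`.
#'
#' @inheritParams align_pair
#' @return See [align_pair()].
#' @export
smith_waterman <- function(a, b, matrix = venom_blosum62(),
                           gap_open = 11, gap_extend = 1) {
  align_pair(a, b, type = "local", matrix = matrix,
             gap_open = gap_open, gap_extend = gap_extend)
}

#' Search candidate proteins against a reference venom set
#'
#' Aligns every query locally against every reference entry and reports
#' all matches passing the identity, coverage and score thresholds,
#' flagging the best-scoring reference per query. Queries with no passing
#' match are listed in the `unmatched` attribute.
#'
#' @param queries,refs Named character vectors or
#'   [Biostrings::AAStringSet]s.
#' @param min_identity Minimum percent identity over aligned columns
#'   (default 35).
#' @param min_coverage Minimum aligned fraction of the query (default 0.5).
#' @param min_score Minimum alignment score (default 50).
#' @param matrix,gap_open,gap_extend Passed to [align_pair()].
#' @return A data.frame of passing matches: `query_id`, `reference_id`,
#'   `score`, `percent_identity`, `query_coverage`, span columns, and
#'   `best` (logical). Attribute `unmatched` holds query ids without a
#'   match.
#' @export
search_reference <- function(queries, refs, min_identity = 35,
                             min_coverage = 0.5, min_score = 50,
                             matrix = venom_blosum62(),
                             gap_open = 11, gap_extend = 1) {
  queries <- .named_chars(queries, "queries")
  refs <- .named_chars(refs, "refs")
  empty <- data.frame(query_id = character(), reference_id = character(),
                      score = numeric(), percent_identity = numeric(),
                      query_coverage = numeric(),
                      query_start = integer(), query_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      best = logical())
  if (length(refs) == 0L) {
    warning("empty reference set: all queries unmatched")
    attr(empty, "unmatched") <- names(queries)
    return(empty)
  }
  rows <- list()
  for (q in names(queries)) {
    for (r in names(refs)) {
      al <- align_pair(queries[[q]], refs[[r]], type = "local",
                       matrix = matrix, gap_open = gap_open,
                       gap_extend = gap_extend)
      if (al$score < min_score || al$n_columns == 0L) next
      if (100 * al$identity < min_identity) next
      if (al$query_coverage < min_coverage) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = q, reference_id = r, score = al$score,
        percent_identity = 100 * al$identity,
        query_coverage = al$query_coverage,
        query_start = al$a_span[1L], query_end = al$a_span[2L],
        ref_start = al$b_span[1L], ref_end = al$b_span[2L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    attr(empty, "unmatched") <- names(queries)
    return(empty)
  }
  # best-scoring reference per query; ties broken by reference id
  out <- out[order(out$query_id, -out$score, out$reference_id), , drop = FALSE]
  out$best <- !duplicated(out$query_id)
  rownames(out) <- NULL
  attr(out, "unmatched") <- setdiff(names(queries), out$query_id)
  out
}

.named_chars <- function(x, what) {
  if (!is.character(x)) x <- as.character(x)
  if (length(x) > 0L && (is.null(names(x)) || anyDuplicated(names(x))))
    stop(what, " must carry unique names")
  x
}

#' Synthetic canonical serine protease for triad detection
#'
#' A deterministic, synthetic stand-in for an annotated canonical
#' trypsin: a 260-residue sequence carrying the catalytic-triad residues
#' at the configured alignment columns (His at 70; Asp at 125 and 130;
#' Ser at 240 and 245, 1-based). All other positions are filled
#' reproducibly from the 20-letter alphabet. Substitute a genuine
#' annotated trypsin via the `seq`/`positions` arguments of
#' [detect_catalytic_triad()] when one is available.
#'
#' @param length Total length in residues (default 260).
#' @return A list with `seq` (character) and `positions` (list `H`, `D`,
#'   `S` of 1-based columns).
#' @export
make_canonical_protease <- function(length = 260L) {
  positions <- list(H = 70L, D = c(125L, 130L), S = c(240L, 245L))
  stopifnot(length >= max(unlist(positions)))
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "I", "L", "K",
          "M", "F", "P", "T", "W", "Y", "V")  # filler: no H/D/S/ambiguity
  set <- aa[(seq_len(length) * 7L) %% length(aa) + 1L]
  set[positions$H] <- "H"
  set[positions$D] <- "D"
  set[positions$S] <- "S"
  list(seq = paste(set, collapse = ""), positions = positions)
}

#' Detect the serine-protease catalytic triad in a query
#'
#' Aligns the query to an annotated canonical protease and reads the
#' query residues mapped to the canonical triad columns. Each triad
#' member is `canonical` if the expected residue appears at any of its
#' allowed columns, `substituted:<residue>` if another residue is
#' aligned there, and `undetermined` if gaps cover all allowed columns.
#'
#' @param query A single amino-acid sequence.
#' @param canonical A list with `seq` and `positions` as returned by
#'   [make_canonical_protease()].
#' @param type Alignment type, `"global"` (default) or `"local"`.
#' @param matrix,gap_open,gap_extend Passed to [align_pair()].
#' @return A one-row data.frame: `his_state`, `asp_state`, `ser_state`.
#' @export
detect_catalytic_triad <- function(query, canonical = make_canonical_protease(),
                                   type = "global",
                                   matrix = venom_blosum62(),
                                   gap_open = 11, gap_extend = 1) {
  if (is.null(canonical$seq) || is.null(canonical$positions))
    stop("canonical reference lacks sequence or triad annotations")
  al <- align_pair(query, canonical$seq, type = type, matrix = matrix,
                   gap_open = gap_open, gap_extend = gap_extend)
  qa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
  ca <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
  # canonical column index per alignment column
  canon_pos <- cumsum(ca != "-") + al$b_span[1L]
  member_state <- function(expected, cols) {
    seen <- character(0)
    for (col in cols) {
      k <- which(canon_pos == col & ca != "-")
      if (length(k) == 0L) next  # column outside or gapped out
      r <- qa[k[1L]]
      if (r == expected) return("canonical")
      if (r != "-") seen <- c(seen, r)
    }
    if (length(seen) > 0L) return(paste0("substituted:", seen[[1L]]))
    "undetermined"
  }
  data.frame(
    his_state = member_state("H", canonical$positions$H),
    asp_state = member_state("D", canonical$positions$D),
    ser_state = member_state("S", canonical$positions$S),
    stringsAsFactors = FALSE)
}
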