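#' Digestion parameters for in-silico trypsin digestion
#'
#' Trypsin cleaves C-terminally of lysine (K) and arginine (R) except
#' when the following residue is proline (P). Defaults mirror a typical
#' MS/MS search configuration: up to 2 missed cleavages and peptides of
#' 7--35 residues.
#'
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @param min_len,max_len Peptide length bounds in residues.
#' @return A list of class `digestion_params`.
#' @export
digestion_params <- function(max_missed = 2L, min_len = 7L, max_len = 35L) {
  stopifnot(max_missed >= 0L, min_len >= 1L, min_len <= max_len)
  structure(list(enzyme = "trypsin", max_missed = as.integer(max_missed),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digestion_params")
}

#' In-silico tryptic digestion of a protein
#'
#' Cleaves after K/R not followed by P, then joins 0..`max_missed`
#' adjacent fragments and filters to the configured length range.
#'
#' @param seq A single amino-acid sequence.
#' @param params A [digestion_params()] object.
#' @return A data.frame with columns `peptide`, `start` (1-based position
#'   in `seq`) and `n_missed`. Concatenating the `n_missed == 0` rows (with
#'   no length filter) reproduces the input sequence.
#' @examples
#' digest_protein("MKTAYIAKQR", digestion_params(max_missed = 0, min_len = 1))
#' @export
digest_protein <- function(seq, params = digestion_params()) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L,
            inherits(params, "digestion_params"))
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  # cleavage after position i: K/R at i, next residue not P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)           # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L  # fully-cleaved fragment starts
  ends <- bounds[-1L]
  nf <- length(starts)
  out <- list()
  for (miss in 0:params$max_missed) {
    if (miss >= nf && miss > 0L) break
    i <- seq_len(nf - miss)
    s <- starts[i]; e <- ends[i + miss]
    out[[miss + 1L]] <- data.frame(
      peptide = substring(seq, s, e), start = s,
      n_missed = miss, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  len <- nchar(out$peptide)
  out <- out[len >= params$min_len & len <= params$max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map observed peptides onto the translated protein database
#'
#' Reports every occurrence of every peptide as a contiguous substring of
#' a frame translation. With `il_equivalence` (the default) isoleucine
#' and leucine are treated as one letter, since they are isobaric and
#' indistinguishable by standard MS/MS. `X` (ambiguous codon) and `*`
#' (stop) in the database never match any peptide residue.
#'
#' @param peptides Character vector of observed peptide sequences.
#' @param db Named [Biostrings::AAStringSet] or character vector from
#'   [translate_contigs()].
#' @param il_equivalence Collapse I and L before matching (default TRUE).
#' @return A data.frame with one row per occurrence: `peptide`,
#'   `contig_id`, `frame`, `offset` (0-based position within the frame
#'   translation), `il_collapsed`, `tryptic_nterm`, `tryptic_cterm`.
#' @export
map_peptides <- function(peptides, db, il_equivalence = TRUE) {
  seqs <- as.character(db)
  if (is.null(names(seqs))) stop("db must be named")
  peptides <- as.character(peptides)
  empty <- nchar(peptides) == 0L | is.na(peptides)
  if (any(empty)) {
    warning(sum(empty), " empty peptide(s) skipped")
    peptides <- peptides[!empty]
  }
  # an observed peptide is a plain 20-letter sequence; X, stops and other
  # ambiguity codes cannot be observed and would otherwise match literally
  odd <- grepl("[^ARNDCQEGHILKMFPSTWYV]", peptides)
  if (any(odd)) {
    warning(sum(odd), " peptide(s) with non-standard residues skipped")
    peptides <- peptides[!odd]
  }
  peptides <- unique(peptides)
  key <- if (il_equivalence) function(x) chartr("I", "L", x) else identity
  seqs_k <- key(seqs)
  ids <- parse_protein_id(names(seqs))
  hits <- match_peptides_cpp(key(peptides), unname(seqs_k))
  if (length(hits$peptide) == 0L)
    return(data.frame(peptide = character(), contig_id = character(),
                      frame = character(), offset = integer(),
                      il_collapsed = logical(), tryptic_nterm = logical(),
                      tryptic_cterm = logical()))
  pep <- peptides[hits$peptide]
  ti <- hits$subject
  out <- data.frame(
    peptide = pep,
    contig_id = ids$contig_id[ti], frame = ids$frame[ti],
    offset = hits$pos - 1L,
    il_collapsed = il_equivalence,
    tryptic_nterm = .tryptic_nterm_vec(seqs[ti], hits$pos, pep),
    tryptic_cterm = .tryptic_cterm_vec(seqs[ti], hits$pos, pep),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$peptide, peptides), out$contig_id,
                   out$frame, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.tryptic_nterm_vec <- function(seq, pos, pep) {
  prev <- substr(seq, pos - 1L, pos - 1L)  # "" when pos == 1
  first <- substr(pep, 1L, 1L)
  pos == 1L | prev == "*" | (prev %in% c("K", "R") & first != "P")
}

.tryptic_cterm_vec <- function(seq, pos, pep) {
  end <- pos + nchar(pep) - 1L
  nxt <- substr(seq, end + 1L, end + 1L)   # "" at the frame end
  last <- substr(pep, nchar(pep), nchar(pep))
  nxt == "" | nxt == "*" | (last %in% c("K", "R") & nxt != "P")
}

#' Infer proteomically identified protein candidates
#'
#' Aggregates peptide matches per (contig, frame), keeping pairs with at
#' least `min_peptides` distinct supporting peptides (optionally counting
#' only fully tryptic matches). Each candidate is linked to the longest
#' ORF of its frame translation that contains at least one supporting
#' peptide.
#'
#' @param matches Output of [map_peptides()].
#' @param db The translated database the matches were made against.
#' @param min_peptides Minimum distinct peptides per candidate (default 1).
#' @param require_tryptic Count only matches tryptic at both termini.
#' @param too_small_aa Passed to [classify_orf_completeness()].
#' @return A data.frame of candidates: `protein_id`, `contig_id`, `frame`,
#'   `n_unique_peptides`, ORF coordinates, `completeness`, `orf_seq`.
#' @export
infer_identified_contigs <- function(matches, db, min_peptides = 1L,
                                     require_tryptic = FALSE,
                                     too_small_aa = 30L) {
  stopifnot(min_peptides >= 1L)
  cols <- c("protein_id", "contig_id", "frame", "n_unique_peptides",
            "aa_start", "aa_end", "completeness", "orf_seq")
  if (nrow(matches) == 0L) {
    out <- data.frame(protein_id = character(), contig_id = character(),
                      frame = character(), n_unique_peptides = integer(),
                      aa_start = integer(), aa_end = integer(),
                      completeness = character(), orf_seq = character())
    return(out)
  }
  m <- matches
  if (require_tryptic) m <- m[m$tryptic_nterm & m$tryptic_cterm, , drop = FALSE]
  if (nrow(m) == 0L) return(infer_identified_contigs(m[0L, ], db))
  m$protein_id <- paste0(m$contig_id, "|frame=", m$frame)
  seqs <- as.character(db)
  out <- lapply(split(m, m$protein_id), function(g) {
    n_up <- length(unique(g$peptide))
    if (n_up < min_peptides) return(NULL)
    pid <- g$protein_id[[1L]]
    orfs <- find_orfs(seqs[[pid]])
    # ORFs containing at least one supporting peptide, longest first
    cover <- vapply(seq_len(nrow(orfs)), function(i) {
      any(g$offset >= orfs$aa_start[i] &
            g$offset + nchar(g$peptide) <= orfs$aa_end[i])
    }, TRUE)
    orfs <- orfs[cover, , drop = FALSE]
    if (nrow(orfs) == 0L) {
      orf <- data.frame(aa_start = NA_integer_, aa_end = NA_integer_)
      compl <- NA_character_; oseq <- NA_character_
    } else {
      len <- orfs$aa_end - orfs$aa_start
      orf <- orfs[order(-len, orfs$aa_start)[1L], , drop = FALSE]
      compl <- classify_orf_completeness(orf, too_small_aa = too_small_aa)
      oseq <- substr(seqs[[pid]], orf$aa_start + 1L, orf$aa_end)
    }
    data.frame(protein_id = pid, contig_id = g$contig_id[[1L]],
               frame = g$frame[[1L]], n_unique_peptides = n_up,
               aa_start = orf$aa_start[[1L]], aa_end = orf$aa_end[[1L]],
               completeness = compl, orf_seq = oseq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(infer_identified_contigs(matches[0L, ], db))
  rownames(out) <- NULL
  out[order(out$contig_id, out$frame), cols]
}
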