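#' Translate a contig in all six reading frames
#'
#' Translates a nucleotide sequence in the three forward offsets and the
#' three offsets of its reverse complement, using the standard genetic
#' code. Stop codons translate to `*`; codons containing an ambiguous
#' base (e.g. `N`) translate to `X`. Trailing 1--2 nucleotides that do
#' not fill a codon are dropped.
#'
#' Frames are named `+1`, `+2`, `+3`, `-1`, `-2`, `-3`; frame `-k` is the
#' translation of the reverse complement starting at offset `k - 1`.
#'
#' @param seq A single nucleotide sequence: a character string or a
#'   length-1 [Biostrings::DNAStringSet].
#' @return A named character vector of six amino-acid sequences.
#' @examples
#' six_frame_translate("ATGGCC")
#' @export
six_frame_translate <- function(seq) {
  if (is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- as.character(seq)[[1L]]
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty nucleotide sequence")
  if (grepl("[^ACGTNRYSWKMBDHV]", seq))
    stop("sequence contains non-IUPAC characters")
  x <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(x)
  out <- character(6L)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (k in 1:3) {
    out[k]     <- .translate_frame(x, k)
    out[k + 3] <- .translate_frame(rc, k)
  }
  out
}

.translate_frame <- function(x, offset1) {
  n <- length(x) - offset1 + 1L
  n <- n - n %% 3L
  if (n <= 0L) return("")
  sub <- Biostrings::subseq(x, start = offset1, width = n)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
}

#' Build the six-frame translated protein database
#'
#' Translates every contig in all six reading frames, producing the
#' protein database that observed peptides are matched against. Database
#' entries are whole frame translations, stops included; open reading
#' frames are a separate view (see [find_orfs()]).
#'
#' @param contigs A named [Biostrings::DNAStringSet] or a named character
#'   vector of nucleotide sequences.
#' @return A [Biostrings::AAStringSet] with `6 * length(contigs)` entries
#'   named `"<contig_id>|frame=<f>"`.
#' @export
translate_contigs <- function(contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  stopifnot(is(contigs, "DNAStringSet"), length(contigs) >= 1L)
  ids <- names(contigs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("contigs must carry unique names")
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  rc <- Biostrings::reverseComplement(contigs)
  parts <- vector("list", 6L)
  for (k in 1:3) {
    parts[[k]]      <- .translate_frame_set(contigs, k)
    parts[[k + 3L]] <- .translate_frame_set(rc, k)
  }
  db <- do.call(c, parts)
  names(db) <- paste0(rep(ids, 6L), "|frame=", rep(frames, each = length(contigs)))
  # reorder so the six frames of each contig are adjacent
  db[as.vector(t(matrix(seq_along(db), ncol = 6L)))]
}

.translate_frame_set <- function(x, offset1) {
  n <- Biostrings::width(x) - offset1 + 1L
  n <- pmax(n - n %% 3L, 0L)
  sub <- Biostrings::subseq(x, start = pmin(offset1, Biostrings::width(x) + 1L),
                            width = n)
  Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE)
}

#' Split a protein database identifier into contig id and frame
#' @param id Character vector of `"<contig_id>|frame=<f>"` identifiers.
#' @return A data.frame with columns `contig_id` and `frame`.
#' @export
parse_protein_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)\\|frame=([+-][123])$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed protein id: ", id[bad][1L])
  data.frame(contig_id = vapply(m, `[`, "", 2L),
             frame = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Find open reading frames in a frame translation
#'
#' An ORF is a maximal stop-free segment of the translated frame with at
#' least `min_aa` residues. Each ORF is annotated with whether it begins
#' at a methionine and whether a stop codon bounds it on either side.
#'
#' @param aa_seq A single amino-acid sequence (stops as `*`).
#' @param min_aa Minimum ORF length in residues (default 1).
#' @return A data.frame with 0-based half-open coordinates `aa_start`,
#'   `aa_end`, plus `has_start_codon`, `preceded_by_stop`, `has_stop`
#'   (a stop follows the segment).
#' @export
find_orfs <- function(aa_seq, min_aa = 1L) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L, min_aa >= 1L)
  n <- nchar(aa_seq)
  empty <- data.frame(aa_start = integer(), aa_end = integer(),
                      has_start_codon = logical(),
                      preceded_by_stop = logical(), has_stop = logical())
  if (n == 0L) return(empty)
  res <- strsplit(aa_seq, "", fixed = TRUE)[[1L]]
  is_stop <- res == "*"
  r <- rle(is_stop)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values & r$lengths >= min_aa
  if (!any(keep)) return(empty)
  s <- starts[keep]; e <- ends[keep]
  data.frame(
    aa_start = s - 1L,
    aa_end = e,
    has_start_codon = res[s] == "M",
    preceded_by_stop = s > 1L,
    has_stop = e < n
  )
}

#' Classify the 5'-completeness of an ORF
#'
#' Labels an ORF for the signal-peptide bookkeeping: `too_small` if
#' shorter than `too_small_aa` residues (too short to evaluate a signal
#' peptide); `incomplete_5prime` if it abuts the start of the frame
#' without a start codon (the true N-terminus lies upstream of the
#' contig); `complete` if it begins with a methionine; `no_start` if it
#' is bounded upstream by a stop codon yet contains no initial
#' methionine (not a translatable ORF). 3'-incompleteness (no bounding
#' stop downstream) is reported by `has_stop` in [find_orfs()] and never
#' overrides the 5' status.
#'
#' @param orf A single row of the data.frame returned by [find_orfs()].
#' @param too_small_aa Length threshold in residues (default 30, roughly
#'   the longest signal-peptide window).
#' @return One of `"complete"`, `"incomplete_5prime"`, `"too_small"`,
#'   `"no_start"`.
#' @export
classify_orf_completeness <- function(orf, too_small_aa = 30L) {
  stopifnot(is.data.frame(orf), nrow(orf) == 1L)
  len <- orf$aa_end - orf$aa_start
  if (len <= 0L) stop("inconsistent ORF: aa_end must exceed aa_start")
  if (len < too_small_aa) return("too_small")
  if (orf$has_start_codon) return("complete")
  if (orf$aa_start == 0L && !orf$preceded_by_stop) return("incomplete_5prime")
  "no_start"
}

#' ORF table for a whole protein database
#'
#' Runs [find_orfs()] and [classify_orf_completeness()] over every entry
#' of a translated database, returning the longest ORF per entry (the
#' ORF view used for secretome input and completeness bookkeeping).
#'
#' @param db A named [Biostrings::AAStringSet] or character vector from
#'   [translate_contigs()].
#' @param min_aa,too_small_aa Passed through to the per-entry calls.
#' @return A data.frame keyed by `protein_id` with the longest ORF's
#'   coordinates, its completeness label and its sequence (`orf_seq`),
#'   or zero rows for entries without an ORF of `min_aa` residues.
#' @export
orf_table <- function(db, min_aa = 1L, too_small_aa = 30L) {
  seqs <- as.character(db)
  out <- lapply(names(seqs), function(id) {
    orfs <- find_orfs(seqs[[id]], min_aa = min_aa)
    if (nrow(orfs) == 0L) return(NULL)
    len <- orfs$aa_end - orfs$aa_start
    o <- orfs[order(-len, orfs$aa_start)[1L], , drop = FALSE]
    o$protein_id <- id
    o$completeness <- classify_orf_completeness(o, too_small_aa = too_small_aa)
    o$orf_seq <- substr(seqs[[id]], o$aa_start + 1L, o$aa_end)
    o
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(aa_start = integer(), aa_end = integer(),
                      has_start_codon = logical(), preceded_by_stop = logical(),
                      has_stop = logical(), protein_id = character(),
                      completeness = character(), orf_seq = character()))
  rownames(out) <- NULL
  out[, c("protein_id", "aa_start", "aa_end", "has_start_codon",
          "preceded_by_stop", "has_stop", "completeness", "orf_seq")]
}
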