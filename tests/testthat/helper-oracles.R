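# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# exhaustive global affine-gap alignment score by recursion over all
# monotone alignments (no dynamic programming); gap of length k costs
# open + (k - 1) * ext
bf_global_score <- function(av, bv, mat, open = 11, ext = 1) {
  n <- length(av); m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= n)
      best <- max(best, -(if (prev == "D") ext else open) + rec(i + 1L, j, "D"))
    if (j <= m)
      best <- max(best, -(if (prev == "I") ext else open) + rec(i, j + 1L, "I"))
    best
  }
  rec(1L, 1L, "M")
}

# exhaustive local score: best global score over all substring pairs
bf_local_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  best <- 0
  n <- length(av); m <- length(bv)
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(m)) for (j2 in j1:m)
      best <- max(best, bf_global_score(av[i1:i2], bv[j1:j2], mat, open, ext))
  best
}

# all sequences over `alphabet` of length 1..max_len
all_words <- function(alphabet, max_len) {
  out <- character(0)
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, apply(grid, 1L, paste, collapse = ""))
  }
  out
}

# naive sliding-window peptide scan (with optional I/L collapse)
naive_peptide_scan <- function(peptides, seqs, il = TRUE) {
  key <- if (il) function(x) chartr("I", "L", x) else identity
  rows <- list()
  for (pep in unique(peptides)) {
    pk <- key(pep); L <- nchar(pep)
    for (nm in names(seqs)) {
      sk <- key(seqs[[nm]])
      if (nchar(sk) < L) next
      for (off in 0:(nchar(sk) - L)) {
        if (substr(sk, off + 1L, off + L) == pk)
          rows[[length(rows) + 1L]] <-
            data.frame(peptide = pep, id = nm, offset = off,
                       stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide = character(), id = character(),
                      offset = integer())
  out[order(out$peptide, out$id, out$offset), , drop = FALSE]
}

# one-sided over-representation p-value by enumerating every 2x2 table
# with the observed margins, probabilities from factorials
hyper_tail_oracle <- function(n_test_with, n_test, n_ref_with, n_ref) {
  lchoose_ <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  ks <- max(0L, n_test - (n_ref - n_ref_with)):min(n_test, n_ref_with)
  probs <- vapply(ks, function(k)
    exp(lchoose_(n_ref_with, k) + lchoose_(n_ref - n_ref_with, n_test - k) -
          lchoose_(n_ref, n_test)), 0)
  sum(probs[ks >= n_test_with])
}

# manual BH step-up: min over the tail of p * m / rank, in sorted order
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
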