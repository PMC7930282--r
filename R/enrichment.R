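#' Read a minimal OBO ontology (is_a edges only)
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace` and `is_a`
#' lines, ignoring obsolete terms and all other relationship types. The
#' result must be acyclic; ancestry queries are rooted through the is_a
#' closure.
#'
#' @param path Path to an OBO file.
#' @return A list of class `ontology`: `terms` (data.frame `id`, `name`,
#'   `namespace`) and `parents` (named list of is_a parent ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- names <- spaces <- character(length(starts))
  parents <- vector("list", length(starts))
  keep <- rep(TRUE, length(starts))
  for (i in seq_along(starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\s*$", chunk)]
    chunk <- chunk[!grepl("^\\[", chunk)]
    field <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), chunk, value = TRUE))
      if (length(v) == 0L) NA_character_ else v
    }
    if (any(grepl("^is_obsolete:\\s*true", chunk))) { keep[i] <- FALSE; next }
    ids[i] <- field("id")[1L]
    names[i] <- field("name")[1L]
    spaces[i] <- field("namespace")[1L]
    isa <- field("is_a")
    parents[[i]] <- if (all(is.na(isa))) character(0) else
      trimws(sub("!.*$", "", isa))
  }
  ids <- ids[keep]; names <- names[keep]; spaces <- spaces[keep]
  parents <- parents[keep]
  names(parents) <- ids
  ont <- structure(list(
    terms = data.frame(id = ids, name = names, namespace = spaces,
                       stringsAsFactors = FALSE),
    parents = parents), class = "ontology")
  .check_acyclic(ont)
  ont
}

#' Build an ontology object from term and edge tables
#'
#' Programmatic counterpart of [read_obo()], used by the synthetic study
#' generator.
#'
#' @param terms data.frame with `id`, `name`, `namespace`.
#' @param parents Named list: is_a parent ids per term id.
#' @return An `ontology` object.
#' @export
make_ontology <- function(terms, parents) {
  stopifnot(all(terms$id %in% names(parents)))
  ont <- structure(list(terms = terms, parents = parents[terms$id]),
                   class = "ontology")
  .check_acyclic(ont)
  ont
}

.check_acyclic <- function(ont) {
  state <- new.env(parent = emptyenv())
  visit <- function(id) {
    s <- state[[id]]
    if (identical(s, 1L)) stop("ontology is cyclic at ", id)
    if (identical(s, 2L)) return(invisible())
    state[[id]] <- 1L
    for (p in ont$parents[[id]]) {
      if (!p %in% ont$terms$id) stop("unknown parent term: ", p)
      visit(p)
    }
    state[[id]] <- 2L
    invisible()
  }
  for (id in ont$terms$id) visit(id)
  invisible(ont)
}

#' All is_a ancestors of a term
#'
#' @param ontology An `ontology` object.
#' @param id A term id.
#' @param include_self Include the term itself (default FALSE).
#' @return Character vector of ancestor term ids.
#' @export
term_ancestors <- function(ontology, id, include_self = FALSE) {
  if (!id %in% ontology$terms$id) stop("unknown term id: ", id)
  seen <- character(0)
  queue <- ontology$parents[[id]]
  while (length(queue) > 0L) {
    t <- queue[[1L]]; queue <- queue[-1L]
    if (t %in% seen) next
    seen <- c(seen, t)
    queue <- c(queue, ontology$parents[[t]])
  }
  if (include_self) unique(c(id, seen)) else seen
}

#' Depth of a term below its namespace root
#'
#' Length of the shortest is_a path to a root (a term with no parents).
#'
#' @param ontology An `ontology` object.
#' @param ids Term ids.
#' @return Integer depths (root = 0).
#' @export
term_depth <- function(ontology, ids) {
  memo <- new.env(parent = emptyenv())
  depth1 <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    ps <- ontology$parents[[id]]
    d <- if (length(ps) == 0L) 0L else 1L + min(vapply(ps, depth1, 0L))
    memo[[id]] <- d
    d
  }
  vapply(ids, depth1, 0L)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Annotates every gene to each ancestor of its directly annotated
#' terms, the standard counting convention for GO enrichment.
#'
#' @param ontology An `ontology` object.
#' @param annotations Named list: direct term ids per gene, or a
#'   data.frame with `contig_id` and a `go_terms` column of
#'   pipe-separated ids.
#' @return Named list of full (propagated) term sets per gene.
#' @export
propagate_annotations <- function(ontology, annotations) {
  if (is.data.frame(annotations)) {
    stopifnot(all(c("contig_id", "go_terms") %in% names(annotations)))
    lst <- strsplit(ifelse(is.na(annotations$go_terms), "",
                           annotations$go_terms), "|", fixed = TRUE)
    lst <- lapply(lst, function(x) x[nzchar(x)])
    names(lst) <- annotations$contig_id
    annotations <- lst
  }
  all_terms <- unique(unlist(annotations, use.names = FALSE))
  unknown <- setdiff(all_terms, ontology$terms$id)
  if (length(unknown) > 0L)
    stop("unknown term id(s) in annotations: ",
         paste(unknown, collapse = ", "))
  anc <- lapply(setNames(all_terms, all_terms), term_ancestors,
                ontology = ontology, include_self = TRUE)
  lapply(annotations, function(ts)
    unique(unlist(anc[ts], use.names = FALSE)))
}

#' One-sided Fisher's exact test for term over-representation
#'
#' Tests whether a term is over-represented in the test set relative to
#' the reference (background) set, from the 2x2 table (test-with-term,
#' test-without, rest-with-term, rest-without).
#'
#' @param n_test_with,n_test Term-annotated and total genes in the test
#'   set.
#' @param n_ref_with,n_ref Term-annotated and total genes in the
#'   reference set (which must contain the test set).
#' @return The one-sided (greater) p-value.
#' @export
fisher_enrichment <- function(n_test_with, n_test, n_ref_with, n_ref) {
  if (n_test > n_ref || n_test_with > n_ref_with)
    stop("test set must be contained in the reference set")
  tab <- matrix(c(n_test_with, n_test - n_test_with,
                  n_ref_with - n_test_with,
                  (n_ref - n_test) - (n_ref_with - n_test_with)),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent counts")
  fisher.test(tab, alternative = "greater")$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; adjusted values are
#' bounded by 1 and never smaller than the raw p-value.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Adjusted values in the original order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Reduce an enriched term set to its most specific terms
#'
#' Drops every term that is a proper is_a ancestor of another term in
#' the set, leaving an antichain.
#'
#' @param ids Term ids.
#' @param ontology An `ontology` object.
#' @return The retained (most specific) term ids.
#' @export
reduce_to_most_specific <- function(ids, ontology) {
  ids <- unique(ids)
  if (length(ids) <= 1L) return(ids)
  anc <- unique(unlist(lapply(ids, term_ancestors, ontology = ontology),
                       use.names = FALSE))
  ids[!ids %in% anc]
}

#' GO-term enrichment of a test set against a reference set
#'
#' True-path-propagated Fisher enrichment of every term annotated in
#' the reference set, with BH-FDR control. Enrichment counts contigs
#' (one vote per contig per term).
#'
#' @param test_ids Contig ids of the test set (must be contained in
#'   `ref_ids`).
#' @param ref_ids Contig ids of the reference (background) set.
#' @param annotations Direct annotations (see
#'   [propagate_annotations()]).
#' @param ontology An `ontology` object.
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @param reduce Drop enriched ancestor terms of other enriched terms
#'   from the `enriched` flag report (default TRUE); all tested terms
#'   remain in the table.
#' @return A data.frame sorted by FDR: `term`, `name`, `namespace`,
#'   `depth`, `n_test_with`, `n_test`, `n_ref_with`, `n_ref`,
#'   `p_value`, `fdr`, `enriched`, `most_specific`.
#' @export
enrich_terms <- function(test_ids, ref_ids, annotations, ontology,
                         alpha = 0.05, reduce = TRUE) {
  test_ids <- unique(test_ids); ref_ids <- unique(ref_ids)
  if (!all(test_ids %in% ref_ids))
    stop("test set must be contained in the reference set")
  full <- propagate_annotations(ontology, annotations)
  full <- full[names(full) %in% ref_ids]
  terms <- sort(unique(unlist(full, use.names = FALSE)))
  n_ref <- length(ref_ids); n_test <- length(test_ids)
  has <- function(term, idset)
    sum(vapply(full[names(full) %in% idset], function(ts) term %in% ts, TRUE))
  rows <- lapply(terms, function(tm) {
    nrw <- has(tm, ref_ids); ntw <- has(tm, test_ids)
    data.frame(term = tm, n_test_with = ntw, n_test = n_test,
               n_ref_with = nrw, n_ref = n_ref,
               p_value = fisher_enrichment(ntw, n_test, nrw, n_ref),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$enriched <- out$fdr < alpha
  out$most_specific <- FALSE
  if (any(out$enriched)) {
    keep <- reduce_to_most_specific(out$term[out$enriched], ontology)
    out$most_specific <- out$term %in% keep
    if (reduce) out$enriched <- out$enriched & out$most_specific
  }
  meta <- ontology$terms[match(out$term, ontology$terms$id), ]
  out$name <- meta$name
  out$namespace <- meta$namespace
  out$depth <- term_depth(ontology, out$term)
  out <- out[order(out$fdr, out$p_value, out$term), ]
  rownames(out) <- NULL
  out[, c("term", "name", "namespace", "depth", "n_test_with", "n_test",
          "n_ref_with", "n_ref", "p_value", "fdr", "enriched",
          "most_specific")]
}
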