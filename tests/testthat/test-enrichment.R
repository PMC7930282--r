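ont <- venom_mini_ontology()

test_that("the bundled ontology parses with is_a edges and depths", {
  expect_s3_class(ont, "ontology")
  expect_equal(nrow(ont$terms), 12L)
  expect_equal(ont$parents[["GO:0004252"]], "GO:0004175")
  expect_setequal(
    term_ancestors(ont, "GO:0004252"),
    c("GO:0004175", "GO:0008233", "GO:0016787", "GO:0003824", "GO:0003674"))
  expect_equal(unname(term_depth(ont, c("GO:0003674", "GO:0004252"))),
               c(0L, 5L))
})

test_that("cyclic or dangling ontologies are rejected", {
  terms <- data.frame(id = c("a", "b"), name = c("a", "b"), namespace = "x")
  expect_error(make_ontology(terms, list(a = "b", b = "a")), "cyclic")
  expect_error(make_ontology(terms, list(a = "zzz", b = character(0))),
               "unknown parent")
})

test_that("annotation propagation follows the true-path rule", {
  full <- propagate_annotations(ont, list(g1 = "GO:0004252"))
  expect_setequal(full$g1,
                  c("GO:0004252", "GO:0004175", "GO:0008233", "GO:0016787",
                    "GO:0003824", "GO:0003674"))
  root_only <- propagate_annotations(ont, list(g = "GO:0003674"))
  expect_equal(root_only$g, "GO:0003674")
  expect_error(propagate_annotations(ont, list(g = "GO:9999999")), "unknown")

  # diamond: child with two parents reaches the shared grandparent once
  dia <- make_ontology(
    data.frame(id = c("r", "p1", "p2", "c"), name = "-", namespace = "x"),
    list(r = character(0), p1 = "r", p2 = "r", c = c("p1", "p2")))
  full_d <- propagate_annotations(dia, list(g = "c"))
  expect_equal(sort(full_d$g), c("c", "p1", "p2", "r"))
})

test_that("pipe-separated annotation tables are accepted", {
  tab <- data.frame(contig_id = c("g1", "g2"),
                    go_terms = c("GO:0004252|GO:0005515", ""))
  full <- propagate_annotations(ont, tab)
  expect_true("GO:0005488" %in% full$g1)
  expect_length(full$g2, 0L)
})

test_that("Fisher enrichment equals the exhaustive hypergeometric tail", {
  expect_equal(fisher_enrichment(0, 10, 0, 100), 1)
  expect_equal(fisher_enrichment(5, 10, 10, 100),
               hyper_tail_oracle(5, 10, 10, 100), tolerance = 1e-12)
  # test set equal to the reference: every term has p = 1
  expect_equal(fisher_enrichment(7, 20, 7, 20), 1)
  expect_error(fisher_enrichment(5, 30, 10, 20), "contained")

  set.seed(47)
  for (rep in 1:40) {
    n_ref <- sample(4:12, 1)
    n_test <- sample(1:n_ref, 1)
    n_ref_with <- sample(0:n_ref, 1)
    lo <- max(0, n_test - (n_ref - n_ref_with))
    hi <- min(n_test, n_ref_with)
    n_test_with <- if (lo == hi) lo else sample(lo:hi, 1)
    expect_equal(fisher_enrichment(n_test_with, n_test, n_ref_with, n_ref),
                 hyper_tail_oracle(n_test_with, n_test, n_ref_with, n_ref),
                 tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the manual step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(53)
  for (rep in 1:10) {
    p <- runif(sample(1:30, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj <= 1) && all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))  # monotone in sorted-p order
  }
})

test_that("reduction to most specific terms yields an antichain", {
  expect_equal(reduce_to_most_specific(c("GO:0008233", "GO:0004252"), ont),
               "GO:0004252")
  anti <- c("GO:0004252", "GO:0005515")
  expect_setequal(reduce_to_most_specific(anti, ont), anti)
  chain <- c("GO:0016787", "GO:0008233", "GO:0004175")
  expect_equal(reduce_to_most_specific(chain, ont), "GO:0004175")

  set.seed(59)
  for (rep in 1:20) {
    ids <- sample(ont$terms$id, sample(2:8, 1))
    red <- reduce_to_most_specific(ids, ont)
    for (x in red)
      expect_false(any(setdiff(red, x) %in% term_ancestors(ont, x)))
  }
})

test_that("a term planted at 5x frequency is detected in at least 9/10 seeds", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(1000L + s)
    ref_ids <- paste0("g", 1:1000)
    test_ids <- ref_ids[1:50]
    base_rate <- 0.1
    ann <- lapply(setNames(ref_ids, ref_ids), function(g) {
      terms <- character(0)
      planted_rate <- if (g %in% test_ids) 5 * base_rate else base_rate
      if (runif(1) < planted_rate) terms <- "GO:0004252"
      if (runif(1) < 0.4) terms <- c(terms, "GO:0005515")
      if (length(terms) == 0L) terms <- "GO:0003674"
      terms
    })
    res <- enrich_terms(test_ids, ref_ids, ann, ont, reduce = FALSE)
    if (res$fdr[res$term == "GO:0004252"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("whole-pipeline enrichment flags the planted peptidase signal", {
  pipe <- cached_pipeline()
  enr <- pipe$enrichment
  expect_true("GO:0004252" %in% enr$term[enr$enriched])
  # enriched report is an antichain after reduction
  flagged <- enr$term[enr$enriched]
  for (x in flagged)
    expect_false(any(setdiff(flagged, x) %in% term_ancestors(ont, x)))
  expect_true(all(enr$fdr >= enr$p_value - 1e-12))
})
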