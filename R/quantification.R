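#' RPKM expression value
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = 1e6 * C * 1000 / (N * L) = 1e9 * C / (N * L)`, where `C` is
#' the number of reads uniquely aligned to the contig, `N` the total
#' uniquely aligned reads in the library and `L` the contig length in
#' bases. Vectorised over `C` and `L`.
#'
#' @param C Read count(s), >= 0.
#' @param N Library total, > 0.
#' @param L Contig length(s) in bases, > 0.
#' @return Numeric RPKM value(s).
#' @examples
#' compute_rpkm(10, 1e6, 1000) # 10
#' @export
compute_rpkm <- function(C, N, L) {
  if (any(N <= 0)) stop("N must be positive")
  if (any(L <= 0)) stop("L must be positive")
  if (any(C < 0)) stop("C must be non-negative")
  1e9 * C / (N * L)
}

#' Per-contig expression table
#'
#' Computes RPKM and log2(RPKM) for a count table. log2 is reported only
#' for positive counts (NA otherwise).
#'
#' @param counts A data.frame with columns `contig_id`, `count` and
#'   `length` (bases). The library total is `sum(count)` unless `N` is
#'   given.
#' @param N Optional library total overriding `sum(counts$count)`.
#' @return The input with `rpkm` and `log2_rpkm` columns appended.
#' @export
rpkm_table <- function(counts, N = NULL) {
  stopifnot(all(c("contig_id", "count", "length") %in% names(counts)))
  if (is.null(N)) N <- sum(counts$count)
  counts$rpkm <- compute_rpkm(counts$count, N, counts$length)
  counts$log2_rpkm <- ifelse(counts$count > 0, log2(counts$rpkm), NA_real_)
  counts
}

#' Rank contigs by expression
#'
#' Orders an expression table by descending RPKM, ties broken by contig
#' id, and attaches annotation descriptions.
#'
#' @param records Output of [rpkm_table()].
#' @param annotations Optional annotation data.frame (`contig_id`,
#'   `description`).
#' @return The reordered table, with a `description` column when
#'   annotations are supplied.
#' @export
rank_by_expression <- function(records, annotations = NULL) {
  out <- records[order(-records$rpkm, records$contig_id), , drop = FALSE]
  if (!is.null(annotations))
    out$description <-
      annotations$description[match(out$contig_id, annotations$contig_id)]
  rownames(out) <- NULL
  out
}

#' qPCR amplification efficiency from a dilution series
#'
#' Fits `Ct ~ log10(dilution)` by least squares; the slope `S` gives the
#' amplification efficiency `E = 10^(-1/S) - 1` (E = 1 is perfect
#' doubling per cycle, slope -3.3219).
#'
#' @param ct Numeric Ct values.
#' @param dilution Matching dilution factors (e.g. 1, 0.1, 0.01).
#' @return A list with `S` (slope) and `E` (efficiency).
#' @export
estimate_efficiency <- function(ct, dilution) {
  stopifnot(length(ct) == length(dilution))
  if (length(unique(dilution)) < 2L)
    stop("at least two distinct dilutions are required")
  S <- unname(coef(lm(ct ~ log10(dilution)))[2L])
  if (S >= 0)
    warning("non-negative slope: efficiency is not interpretable")
  list(S = S, E = 10^(-1 / S) - 1)
}

#' Efficiency-corrected relative expression (Pfaffl form)
#'
#' Ratio of target-gene expression in a test sample versus a calibrator
#' sample, normalised by one or more reference genes:
#' `ratio = (1 + E_t)^(Ct_cal - Ct_test) / geomean_r (1 + E_r)^(Ct_r,cal - Ct_r,test)`.
#' With all efficiencies equal to 1 this reduces to the classical
#' `2^-ddCt`. Multiple reference genes are combined by the geometric
#' mean of their per-gene normalisation factors.
#'
#' @param ct_target_test,ct_target_cal Target-gene Ct in the test and
#'   calibrator samples.
#' @param ct_ref_test,ct_ref_cal Numeric vectors of reference-gene Ct
#'   values (one per reference gene), in matching order.
#' @param E_target Target amplification efficiency, in (0, 1.1].
#' @param E_refs Reference efficiencies (recycled to the number of
#'   reference genes), in (0, 1.1].
#' @return The expression ratio (positive scalar).
#' @export
relative_expression <- function(ct_target_test, ct_target_cal,
                                ct_ref_test, ct_ref_cal,
                                E_target = 1, E_refs = 1) {
  stopifnot(length(ct_ref_test) == length(ct_ref_cal))
  E_refs <- rep_len(E_refs, length(ct_ref_test))
  if (any(c(E_target, E_refs) <= 0) || any(c(E_target, E_refs) > 1.1))
    stop("efficiencies must lie in (0, 1.1]")
  num <- (1 + E_target)^(ct_target_cal - ct_target_test)
  ref_factors <- (1 + E_refs)^(ct_ref_cal - ct_ref_test)
  num / exp(mean(log(ref_factors)))
}

#' Compare replicate expression ratios between two groups
#'
#' Classical unpaired t-test (equal variances by default; Welch behind a
#' flag) with per-group mean and standard error of the mean.
#'
#' @param a,b Numeric vectors of replicate values (>= 2 each).
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @return A list: `t`, `p_value`, `df`, `mean_a`, `sem_a`, `mean_b`,
#'   `sem_b`.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two replicates")
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_a = mean(a), sem_a = sd(a) / sqrt(length(a)),
       mean_b = mean(b), sem_b = sd(b) / sqrt(length(b)))
}

#' Full qPCR analysis of a Ct table
#'
#' For each target gene: estimates amplification efficiencies from the
#' calibrator group's dilution series (technical replicates averaged),
#' computes per-biological-replicate expression ratios versus the
#' calibrator-group mean at dilution 1 using [relative_expression()]
#' with the named reference genes, and compares the two groups with
#' [compare_groups()].
#'
#' @param qpcr A data.frame with columns `gene`, `group`, `dilution`,
#'   `bio_rep`, `tech_rep`, `ct`.
#' @param reference_genes Names of the reference genes in `gene`.
#' @param calibrator_group,test_group Group labels.
#' @param var_equal Passed to [compare_groups()].
#' @return A data.frame with one row per target gene: `gene`, `E`,
#'   `ratio` (test-group mean), `sem`, `calibrator_ratio`,
#'   `calibrator_sem`, `t`, `p_value`.
#' @export
analyze_qpcr <- function(qpcr, reference_genes = c("GAPDH", "beta-tubulin"),
                         calibrator_group = "body",
                         test_group = "venom_gland",
                         var_equal = TRUE) {
  need <- c("gene", "group", "dilution", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(qpcr)))
  genes <- unique(qpcr$gene)
  targets <- setdiff(genes, reference_genes)
  if (!all(reference_genes %in% genes))
    stop("reference gene absent from table: ",
         setdiff(reference_genes, genes)[[1L]])

  # efficiencies from the calibrator group's dilution series
  eff <- vapply(genes, function(g) {
    d <- qpcr[qpcr$gene == g & qpcr$group == calibrator_group, , drop = FALSE]
    ag <- aggregate(ct ~ dilution, data = d, FUN = mean)
    estimate_efficiency(ag$ct, ag$dilution)$E
  }, 0)

  # mean Ct per gene, group and biological replicate at dilution 1
  base <- qpcr[qpcr$dilution == 1, , drop = FALSE]
  ct_of <- function(g, grp) {
    d <- base[base$gene == g & base$group == grp, , drop = FALSE]
    ag <- aggregate(ct ~ bio_rep, data = d, FUN = mean)
    setNames(ag$ct, ag$bio_rep)
  }

  rows <- lapply(targets, function(g) {
    cal_t <- mean(ct_of(g, calibrator_group))
    cal_r <- vapply(reference_genes,
                    function(r) mean(ct_of(r, calibrator_group)), 0)
    ratio_in <- function(grp) {
      reps <- sort(unique(base$bio_rep[base$group == grp]))
      vapply(reps, function(b) {
        relative_expression(
          ct_target_test = ct_of(g, grp)[[as.character(b)]],
          ct_target_cal = cal_t,
          ct_ref_test = vapply(reference_genes, function(r)
            ct_of(r, grp)[[as.character(b)]], 0),
          ct_ref_cal = cal_r,
          E_target = eff[[g]], E_refs = eff[reference_genes])
      }, 0)
    }
    r_test <- ratio_in(test_group)
    r_cal <- ratio_in(calibrator_group)
    cmp <- tryCatch(compare_groups(r_test, r_cal, var_equal = var_equal),
                    error = function(e) list(  # zero-variance degenerate case
                      t = NA_real_, p_value = NA_real_,
                      mean_a = mean(r_test), sem_a = sd(r_test) / sqrt(length(r_test)),
                      mean_b = mean(r_cal), sem_b = sd(r_cal) / sqrt(length(r_cal))))
    data.frame(gene = g, E = eff[[g]],
               ratio = cmp$mean_a, sem = cmp$sem_a,
               calibrator_ratio = cmp$mean_b, calibrator_sem = cmp$sem_b,
               t = cmp$t, p_value = cmp$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
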