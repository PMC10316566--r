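# Evaluation statistics: detection overlap, profile and p-value rank
# correlations, DEG recapitulation (overall, quartile-stratified, and for
# the modest-DEG subset), and the orchestration of the full sampling grid.

#' Detection overlap between two abundance profiles
#'
#' A gene counts as detected when its TPM is greater than zero. Profiles
#' are aligned on the union of their gene IDs (missing genes count as
#' undetected).
#'
#' @param a,b Named numeric vectors of per-gene TPM.
#' @return Named integer vector `c(n_a_only, n_b_only, n_both)`.
#' @export
detection_overlap <- function(a, b) {
  genes <- union(names(a), names(b))
  da <- genes[genes %in% names(a)[a > 0]]
  db <- genes[genes %in% names(b)[b > 0]]
  c(n_a_only = length(setdiff(da, db)),
    n_b_only = length(setdiff(db, da)),
    n_both = length(intersect(da, db)))
}

#' Spearman correlation of two abundance profiles
#'
#' Rank correlation (midranks for ties) of `log2(TPM + 1)` over the union
#' of the gene universes; genes undetected in one profile enter as 0 TPM.
#'
#' @param a,b Named numeric vectors of per-gene TPM.
#' @return Spearman's rho. Errors if either aligned vector has zero
#'   variance.
#' @export
profile_correlation <- function(a, b) {
  genes <- union(names(a), names(b))
  x <- log2(ifelse(genes %in% names(a), a[genes], 0) + 1)
  y <- log2(ifelse(genes %in% names(b), b[genes], 0) + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' DEG recapitulation of a reference set by a test set
#'
#' @param reference_degs Character vector of reference (bulk) DEGs.
#' @param test_degs Character vector of DEGs called by the test analysis.
#' @return List with `rate` (`|reference intersect test| / |reference|`),
#'   `n_overlap`, and `n_unique_to_test` (`|test setdiff reference|`, the
#'   DEGs unique to the test analysis).
#' @export
recapitulation <- function(reference_degs, test_degs) {
  if (length(reference_degs) == 0)
    stop("empty reference DEG set: rate undefined")
  ov <- length(intersect(reference_degs, test_degs))
  list(rate = ov / length(reference_degs),
       n_overlap = ov,
       n_unique_to_test = length(setdiff(test_degs, reference_degs)))
}

#' Quartile-stratified recapitulation
#'
#' Partitions the reference DEGs into quartiles by one of three keys taken
#' from the reference DE table — unadjusted p-value (Q1 = smallest),
#' absolute log2 fold change (Q1 = largest), or transcript abundance
#' `mean_tpm` (Q1 = highest) — and computes the recapitulation rate within
#' each quartile. Ties break by ascending gene ID.
#'
#' @param reference_de `DEResult` table of the reference analysis.
#' @param reference_degs Reference DEG IDs (must appear in
#'   `reference_de`).
#' @param test_degs DEGs called by the test analysis.
#' @param stratifier One of `"p"`, `"abs_log2fc"`, `"abundance"`.
#' @return Numeric vector of four rates, named `Q1`–`Q4`.
#' @export
stratified_recapitulation <- function(reference_de, reference_degs,
                                      test_degs,
                                      stratifier = c("p", "abs_log2fc",
                                                     "abundance")) {
  stratifier <- match.arg(stratifier)
  ref <- reference_de[match(reference_degs, reference_de$gene_id), ,
                      drop = FALSE]
  if (anyNA(ref$gene_id)) stop("reference_degs must appear in reference_de")
  key <- switch(stratifier,
                p = ref$p_unadj,
                abs_log2fc = abs(ref$log2fc),
                abundance = ref$mean_tpm)
  q <- assign_quartiles(key, ref$gene_id,
                        decreasing = stratifier != "p")
  hit <- ref$gene_id %in% test_degs
  vapply(paste0("Q", 1:4), function(l) mean(hit[q == l]), 0)
}

#' Criteria defining the modest-DEG subset
#'
#' Interval conditions (all inclusive) isolating reference DEGs with
#' moderate significance and effect size — a proxy for the modest
#' condition-vs-condition differences typical of within-cell-type
#' comparisons. Defaults: unadjusted p in `[3.1e-5, 0.025]`, BH-adjusted
#' p in `[1e-4, 0.05]`, absolute log2 fold change in `[0.5, 2]`.
#'
#' @param p_unadj_range,p_adj_range,abs_log2fc_range Length-2 ordered
#'   intervals.
#' @return A list of class `ModestDEGCriteria`.
#' @export
modest_deg_criteria <- function(p_unadj_range = c(3.1e-5, 0.025),
                                p_adj_range = c(1e-4, 0.05),
                                abs_log2fc_range = c(0.5, 2)) {
  for (r in list(p_unadj_range, p_adj_range, abs_log2fc_range))
    stopifnot(length(r) == 2, r[1] <= r[2])
  structure(list(p_unadj_range = p_unadj_range,
                 p_adj_range = p_adj_range,
                 abs_log2fc_range = abs_log2fc_range),
            class = "ModestDEGCriteria")
}

#' Select the modest-DEG subset of a reference DE table
#'
#' @param reference_de `DEResult` table.
#' @param criteria A [modest_deg_criteria()].
#' @return Character vector of gene IDs satisfying all three interval
#'   conditions (inclusive bounds).
#' @export
modest_deg_subset <- function(reference_de,
                              criteria = modest_deg_criteria()) {
  stopifnot(inherits(criteria, "ModestDEGCriteria"))
  within <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  keep <- within(reference_de$p_unadj, criteria$p_unadj_range) &
    within(reference_de$p_bh, criteria$p_adj_range) &
    within(abs(reference_de$log2fc), criteria$abs_log2fc_range)
  reference_de$gene_id[keep]
}

#' Spearman correlation of p-values over a gene set
#'
#' Rank correlation of the unadjusted p-values of the two analyses over
#' `gene_set` (normally the reference DEG set, so the set is fixed across
#' sampling levels and correlations are comparable). Genes missing or
#' untested (`NA`) on the test side enter with p = 1.
#'
#' @param reference_de,test_de `DEResult` tables.
#' @param gene_set Gene IDs to correlate over (>= 3).
#' @return Spearman's rho.
#' @export
pvalue_correlation <- function(reference_de, test_de, gene_set) {
  if (length(gene_set) < 3) stop("need >= 3 genes")
  pr <- reference_de$p_unadj[match(gene_set, reference_de$gene_id)]
  if (anyNA(pr)) stop("reference_de must cover gene_set with finite p")
  pt <- test_de$p_unadj[match(gene_set, test_de$gene_id)]
  pt[is.na(pt)] <- 1
  stats::cor(pr, pt, method = "spearman")
}

eval_stats_row <- function(axis, method, level, rep_index, reference_de,
                           reference_degs, modest_degs, test_de, test_degs,
                           adjustment, ref_tpm, test_tpm) {
  rec <- recapitulation(reference_degs, test_degs)
  quart <- lapply(c(p = "p", lfc = "abs_log2fc", tpm = "abundance"),
                  function(s) stratified_recapitulation(
                    reference_de, reference_degs, test_degs, s))
  modest_rate <- if (length(modest_degs))
    recapitulation(modest_degs, test_degs)$rate else NA_real_
  row <- data.frame(
    axis = axis, method = method, level = level, rep = rep_index,
    adjustment = adjustment,
    n_degs_reference = length(reference_degs),
    n_degs_test = length(test_degs),
    n_overlap = rec$n_overlap,
    recapitulation_rate = rec$rate,
    unique_to_test = rec$n_unique_to_test,
    modest_recapitulation = modest_rate,
    spearman_p = pvalue_correlation(reference_de, test_de, reference_degs),
    spearman_abundance = profile_correlation(ref_tpm, test_tpm),
    stringsAsFactors = FALSE)
  for (s in names(quart))
    for (k in 1:4) row[[sprintf("q_%s_%d", s, k)]] <- quart[[s]][k]
  row
}

#' Run the full down-sampling evaluation grid
#'
#' The orchestration behind the whole analysis. The reference is the NB
#' Wald test with BH adjustment on the full bulk data. Then, for every
#' cell fraction and repeat of the plan, the single-cell data are
#' subsampled and analyzed two ways — pseudo-bulk (per cell type x
#' replicate library) with the NB test and BH adjustment, and directly
#' with the Wilcoxon test under BH and, separately, Bonferroni adjustment
#' — and every comparison statistic is computed against the bulk
#' reference. For every read depth of the plan, the bulk data are thinned
#' and re-tested, with the largest depth serving as the reference of that
#' axis.
#'
#' @param sc Sparse [count_matrix()] of cells (already cell-filtered, or
#'   pass `filter_params` to filter here).
#' @param bulk [count_matrix()] of bulk replicate counts.
#' @param lengths Named gene-length vector covering all genes.
#' @param plan A [sampling_plan()].
#' @param filter_params Optional [cell_filter_params()]; applied once,
#'   before any subsampling.
#' @param alpha Significance level for all DEG calls.
#' @param criteria A [modest_deg_criteria()].
#' @param scale_factor LogNormalize scale factor for the Wilcoxon path.
#' @return List with `report` (tidy data.frame, one row per axis x method
#'   x level x repeat), `reference_de` (bulk `DEResult`), and
#'   `reference_degs`.
#' @export
run_full_evaluation <- function(sc, bulk, lengths, plan = sampling_plan(),
                                filter_params = NULL, alpha = 0.05,
                                criteria = modest_deg_criteria(),
                                scale_factor = 1e4) {
  stopifnot(inherits(plan, "SamplingPlan"))
  if (!is.null(filter_params)) sc <- filter_cells(sc, filter_params)

  bulk_tpm <- tpm(bulk, lengths)
  bulk_mean_tpm <- rowMeans(bulk_tpm)
  reference_de <- nb_wald_test(bulk, mean_tpm = bulk_mean_tpm)
  reference_degs <- call_degs(reference_de, alpha, "BH")
  modest_degs <- modest_deg_subset(reference_de, criteria)

  rows <- list()
  for (f in plan$cell_fractions) {
    for (r in seq_len(plan$n_repeats)) {
      if (f == 1 && r > 1) {            # deterministic level: copy repeat 1
        prev <- rows[(length(rows) - 2L):length(rows)]
        for (row in prev) {
          row$rep <- r
          rows[[length(rows) + 1L]] <- row
        }
        next
      }
      sub <- subsample_cells(sc, f, r, plan$seed)
      pb <- pseudo_bulk(sub)
      pb_tpm_mat <- tpm(pb, lengths)
      pb_tpm <- rowMeans(pb_tpm_mat)
      pb_de <- nb_wald_test(pb, mean_tpm = pb_tpm)
      rows[[length(rows) + 1L]] <- eval_stats_row(
        "cells", "pseudobulk_nb", f, r, reference_de, reference_degs,
        modest_degs, pb_de, call_degs(pb_de, alpha, "BH"), "BH",
        bulk_mean_tpm, pb_tpm)

      wx <- wilcoxon_rank_sum(log_normalize(sub, scale_factor),
                              mean_tpm = pb_tpm)
      rows[[length(rows) + 1L]] <- eval_stats_row(
        "cells", "wilcoxon", f, r, reference_de, reference_degs,
        modest_degs, wx, call_degs(wx, alpha, "BH"), "BH",
        bulk_mean_tpm, pb_tpm)
      rows[[length(rows) + 1L]] <- eval_stats_row(
        "cells", "wilcoxon", f, r, reference_de, reference_degs,
        modest_degs, wx, call_degs(wx, alpha, "bonferroni"), "bonferroni",
        bulk_mean_tpm, pb_tpm)
    }
  }

  if (length(plan$read_depths)) {
    ref_depth <- plan$read_depths[1]
    thin_ref <- thin_reads(bulk, ref_depth, plan$seed)
    thin_ref_tpm <- rowMeans(tpm(thin_ref, lengths))
    depth_ref_de <- nb_wald_test(thin_ref, mean_tpm = thin_ref_tpm)
    depth_ref_degs <- call_degs(depth_ref_de, alpha, "BH")
    depth_modest <- modest_deg_subset(depth_ref_de, criteria)
    for (d in plan$read_depths) {
      thin <- if (d == ref_depth) thin_ref else thin_reads(bulk, d, plan$seed)
      t_tpm <- rowMeans(tpm(thin, lengths))
      t_de <- if (d == ref_depth) depth_ref_de else
        nb_wald_test(thin, mean_tpm = t_tpm)
      rows[[length(rows) + 1L]] <- eval_stats_row(
        "depth", "bulk_nb", d, 1L, depth_ref_de, depth_ref_degs,
        depth_modest, t_de, call_degs(t_de, alpha, "BH"), "BH",
        thin_ref_tpm, t_tpm)
    }
  }

  list(report = do.call(rbind, rows),
       reference_de = reference_de,
       reference_degs = reference_degs)
}
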