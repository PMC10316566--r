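test_that("detection_overlap does Venn arithmetic on TPM > 0", {
  a <- c(g1 = 5, g2 = 1, g3 = 2, g4 = 0)
  b <- c(g1 = 0, g2 = 3, g3 = 1, g4 = 7)
  expect_equal(detection_overlap(a, b),
               c(n_a_only = 1L, n_b_only = 1L, n_both = 2L))
  expect_equal(unname(detection_overlap(a, a)), c(0L, 0L, 3L))
  disj <- c(g5 = 1, g6 = 2)
  expect_equal(unname(detection_overlap(a, disj)), c(3L, 2L, 0L))
})

test_that("profile_correlation is Spearman on log2(TPM + 1) with zero fill", {
  a <- c(g1 = 1, g2 = 10, g3 = 100, g4 = 1000)
  expect_equal(profile_correlation(a, a^2), 1)       # monotone transform
  rev <- stats::setNames(base::rev(unname(a)), names(a))
  expect_equal(profile_correlation(a, rev), -1)
  b <- c(g1 = 1, g2 = 3, g3 = 2, g4 = 4)
  expect_equal(profile_correlation(a, b), 0.8)
  expect_equal(profile_correlation(a, b), rank_pearson(a, b))
  # missing genes enter as zero TPM
  expect_equal(profile_correlation(a, b[1:3]),
               profile_correlation(a, c(b[1:3], g4 = 0)))
  expect_error(profile_correlation(a, c(g1 = 1, g2 = 1, g3 = 1, g4 = 1)),
               "zero variance")
})

test_that("recapitulation computes rate, overlap and test-unique counts", {
  r <- recapitulation(c("A", "B", "C", "D"), c("B", "C", "E"))
  expect_equal(r$rate, 0.5)
  expect_equal(r$n_overlap, 2)
  expect_equal(r$n_unique_to_test, 1)
  full <- recapitulation(c("A", "B"), c("A", "B"))
  expect_equal(full$rate, 1)
  expect_equal(full$n_unique_to_test, 0)
  expect_equal(recapitulation(c("A", "B"), c("X"))$rate, 0)
  expect_error(recapitulation(character(0), "A"), "empty reference")
})

ref_table <- function(n = 8) {
  p <- 10^seq(-20, -2, length.out = n)
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             base_mean = 10, log2fc = seq(4, 0.5, length.out = n),
             stat = 1, p_unadj = p, p_bh = p.adjust(p, "BH"),
             p_bonf = pmin(1, p * n),
             mean_tpm = seq(1000, 5, length.out = n))
}

test_that("stratified_recapitulation partitions by key direction", {
  de <- ref_table()
  ref <- de$gene_id
  expect_equal(unname(stratified_recapitulation(de, ref, ref, "p")),
               rep(1, 4))
  # test set = top half by p: quartiles (1, 1, 0, 0)
  top <- ref[1:4]
  expect_equal(unname(stratified_recapitulation(de, ref, top, "p")),
               c(1, 1, 0, 0))
  # same for the descending keys (top half = largest lfc / highest TPM)
  expect_equal(unname(stratified_recapitulation(de, ref, top, "abs_log2fc")),
               c(1, 1, 0, 0))
  expect_equal(unname(stratified_recapitulation(de, ref, top, "abundance")),
               c(1, 1, 0, 0))
  # minimal case: 4 DEGs, test holds only Q1's gene
  de4 <- de[1:4, ]
  expect_equal(unname(stratified_recapitulation(de4, de4$gene_id,
                                                de4$gene_id[1], "p")),
               c(1, 0, 0, 0))
})

test_that("modest_deg_subset applies inclusive interval bounds", {
  crit <- modest_deg_criteria()
  de <- data.frame(gene_id = c("in", "bigfc", "edge", "tiny_p"),
                   p_unadj = c(1e-3, 1e-3, 3.1e-5, 1e-30),
                   p_bh = c(0.01, 0.01, 1e-4, 1e-28),
                   log2fc = c(1, 3, 0.5, 1))
  expect_equal(modest_deg_subset(de, crit), c("in", "edge"))
  # |log2fc| exactly 2 still included
  de$log2fc[2] <- 2
  expect_true("bigfc" %in% modest_deg_subset(de, crit))
  expect_error(modest_deg_criteria(p_adj_range = c(0.05, 1e-4)))
})

test_that("pvalue_correlation ranks p-values over a fixed gene set with p = 1 fill", {
  de <- ref_table()
  expect_equal(pvalue_correlation(de, de, de$gene_id), 1)
  flipped <- de; flipped$p_unadj <- base::rev(de$p_unadj)
  expect_equal(pvalue_correlation(de, flipped, de$gene_id), -1)
  set.seed(2)
  t2 <- de; t2$p_unadj <- runif(8)
  expect_equal(pvalue_correlation(de, t2, de$gene_id),
               rank_pearson(de$p_unadj, t2$p_unadj))
  # missing test-side genes enter as p = 1
  part <- t2[1:6, ]
  filled <- t2; filled$p_unadj[7:8] <- 1
  expect_equal(pvalue_correlation(de, part, de$gene_id),
               rank_pearson(de$p_unadj, filled$p_unadj))
  expect_error(pvalue_correlation(de, t2, de$gene_id[1:2]), ">= 3")
})

test_that("run_full_evaluation produces a complete, in-range report grid", {
  sim <- small_sim(seed = 55, n_genes = 300, n_cells = 180, frac_de = 0.3,
                   bulk_depth = 8e5)
  plan <- sampling_plan(cell_fractions = c(1, 0.3), n_repeats = 2,
                        read_depths = c(5e5, 1e5), seed = 4)
  res <- run_full_evaluation(sim$sc, sim$bulk, sim$lengths, plan)
  rep <- res$report

  # row count: 3 methods x fractions x repeats + depths
  expect_equal(nrow(rep), 3 * 2 * 2 + 2)
  expect_equal(sum(rep$axis == "depth"), 2)

  # fraction 1.0: all repeats identical
  full <- rep[rep$axis == "cells" & rep$level == 1, ]
  for (m in unique(full$method))
    for (adj in unique(full$adjustment[full$method == m])) {
      rr <- full[full$method == m & full$adjustment == adj, ]
      expect_equal(rr$recapitulation_rate[1], rr$recapitulation_rate[2])
      expect_equal(rr$n_degs_test[1], rr$n_degs_test[2])
    }

  rate_cols <- c("recapitulation_rate", "modest_recapitulation",
                 grep("^q_", names(rep), value = TRUE))
  for (cl in rate_cols) {
    v <- rep[[cl]][!is.na(rep[[cl]])]
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_true(all(rep$n_overlap <= pmin(rep$n_degs_reference, rep$n_degs_test)))
  expect_true(all(abs(rep$spearman_p) <= 1))

  # reference level of the depth axis recapitulates itself exactly
  depth_ref <- rep[rep$axis == "depth" & rep$level == 5e5, ]
  expect_equal(depth_ref$recapitulation_rate, 1)
  expect_equal(depth_ref$spearman_p, 1)
})

test_that("plans without depth levels and a single fraction reduce to the full data", {
  sim <- small_sim(seed = 56, n_genes = 200, n_cells = 120, bulk_depth = 6e5)
  plan <- sampling_plan(cell_fractions = 1, n_repeats = 3,
                        read_depths = numeric(0), seed = 1)
  res <- run_full_evaluation(sim$sc, sim$bulk, sim$lengths, plan)
  expect_equal(nrow(res$report), 9)
  expect_true(all(res$report$axis == "cells"))
  expect_equal(unique(res$report$level), 1)
})
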