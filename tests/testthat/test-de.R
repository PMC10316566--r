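test_that("median-of-ratios size factors match hand-computed cases", {
  # sample2 = 2 x sample1 exactly: factors proportional to (1, 2)
  m <- matrix(c(4, 10, 20, 8, 20, 40), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sf <- size_factors_median_of_ratios(make_cm(m))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)

  # identical columns: all factors equal
  same <- make_cm(cbind(s1 = c(3, 7), s2 = c(3, 7), s3 = c(3, 7)))
  expect_equal(unname(size_factors_median_of_ratios(same)), rep(1, 3))

  # worked 3x2 example: reference = geometric means, factors (1/sqrt(2), sqrt(2))
  w <- matrix(c(2, 6, 10, 4, 12, 20), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors_median_of_ratios(make_cm(w))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # genes with a zero anywhere are excluded from the reference set
  z <- w; z[1, 1] <- 0
  expect_equal(unname(size_factors_median_of_ratios(make_cm(z))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  allz <- make_cm(cbind(s1 = c(0, 5), s2 = c(3, 0)))
  expect_error(size_factors_median_of_ratios(allz), "cannot normalize")
})

test_that("adjust_pvalues matches the step-up definition and propagates NAs", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03, 0.002), "BH"),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(c(0.3, 0.4, 0.5, 0.6), "bonferroni")[1], 1)

  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    expect_equal(adjust_pvalues(p, "BH"), brute_bh(p))
  }

  p <- c(0.01, NA, 0.2)
  expect_equal(adjust_pvalues(p, "BH"), c(0.02, NA, 0.2))
  expect_equal(adjust_pvalues(p, "bonferroni"), c(0.02, NA, 0.4))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_degs uses an inclusive threshold", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    p_bh = c(0.05, 0.050001, NA),
                    p_bonf = c(0.2, 0.01, NA))
  expect_equal(call_degs(res, 0.05, "BH"), "a")
  expect_equal(call_degs(res, 0.05, "bonferroni"), "b")
  expect_equal(call_degs(res[0, ], 0.05), character(0))
  expect_equal(call_degs(res, 1), c("a", "b"))
})

test_that("NB Wald test agrees with the Poisson two-group closed form at the dispersion floor", {
  set.seed(5)
  ng <- 40
  counts <- matrix(rpois(ng * 6, 80), ng,
                   dimnames = list(sprintf("g%02d", 1:ng), sprintf("s%d", 1:6)))
  cm <- make_cm(counts, group = rep(c("A", "B"), each = 3))
  res <- nb_wald_test(cm, dispersions = 1e-8)
  sf <- size_factors_median_of_ratios(cm)
  for (g in c(1, 7, 25)) {
    oracle <- poisson_two_group(counts[g, ], sf, 1:3, 4:6)
    expect_equal(res$log2fc[g], oracle$beta / log(2), tolerance = 1e-5)
    se_impl <- (res$log2fc[g] * log(2)) / res$stat[g]
    expect_equal(se_impl, oracle$se, tolerance = 1e-3)
  }
})

test_that("NB Wald test recovers simulated log2 fold changes and is well-behaved under the null", {
  set.seed(17)
  ng <- 1000; n_de <- 200                # sign-balanced DE genes amid a null
  lfc <- c(rep(2, 100), rep(-2, 100), rep(0, ng - n_de))
  counts <- cbind(
    matrix(rnbinom(ng * 3, mu = 100, size = 1 / 0.05), ng),
    matrix(rnbinom(ng * 3, mu = 100 * 2^lfc, size = 1 / 0.05), ng))
  dimnames(counts) <- list(sprintf("g%04d", 1:ng), sprintf("s%d", 1:6))
  res <- nb_wald_test(make_cm(counts, group = rep(c("A", "B"), each = 3)))
  est <- mean(sign(lfc[1:n_de]) * res$log2fc[1:n_de])
  expect_gt(est, 1.8)
  expect_lt(est, 2.2)

  # null: identical group means, large counts -> centered log2fc, roughly
  # uniform p-values (no excess of small p)
  null_counts <- matrix(rnbinom(ng * 6, mu = 500, size = 1 / 0.02), ng,
                        dimnames = dimnames(counts))
  rnull <- nb_wald_test(make_cm(null_counts, group = rep(c("A", "B"), each = 3)))
  expect_lt(abs(mean(rnull$log2fc)), 0.05)
  expect_lt(mean(rnull$p_unadj <= 0.05), 0.1)
})

test_that("NB Wald test handles all-zero and one-group-zero genes", {
  set.seed(2)
  counts <- matrix(rpois(10 * 6, 50), 10,
                   dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  counts[1, ] <- 0                 # all zero
  counts[2, 1:3] <- 0              # zero in group A only
  res <- nb_wald_test(make_cm(counts, group = rep(c("A", "B"), each = 3)))
  expect_true(is.na(res$p_unadj[1]) && is.na(res$log2fc[1]))
  expect_true(is.finite(res$stat[2]) && res$log2fc[2] > 0)
  # all-zero gene excluded from m: BH of remaining genes unaffected by it
  expect_equal(res$p_bh[-1], adjust_pvalues(res$p_unadj[-1], "BH"))
  expect_error(nb_wald_test(make_cm(counts, group = c("A", rep("B", 5)))),
               "no replication")
})

test_that("Wilcoxon p-values match exact enumeration for small untied groups", {
  # {1,2,3} vs {4,5,6}: exact two-sided permutation p = 2/20 = 0.1
  nm <- make_norm(matrix(1:6, 1), rep(c("A", "B"), each = 3))
  res <- wilcoxon_rank_sum(nm)
  expect_equal(exact_wilcoxon_p(1:3, 4:6), 0.1)
  expect_lt(abs(res$p_unadj - 0.1), 0.02)

  # randomized cases use group sizes 5-8: the normal approximation with
  # continuity correction stays within 0.02 of exact enumeration there
  # (smaller groups can reach ~0.04 at mid-range p)
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    vals <- sample(seq(0.5, 20, by = 0.5), n1 + n2)   # untied, nonzero
    nm <- make_norm(matrix(vals, 1), rep(c("A", "B"), c(n1, n2)))
    p_exact <- exact_wilcoxon_p(vals[seq_len(n1)], vals[n1 + seq_len(n2)])
    expect_lt(abs(wilcoxon_rank_sum(nm)$p_unadj - p_exact), 0.02)
  }
})

test_that("Wilcoxon handles ties, zeros and exchangeable nulls like the reference implementation", {
  set.seed(13)
  n1 <- 25; n2 <- 35; ng <- 150
  m <- matrix(rpois(ng * (n1 + n2), 0.7), ng,
              dimnames = list(sprintf("g%03d", 1:ng), sprintf("c%02d", 1:(n1 + n2))))
  cm <- make_cm(m, group = rep(c("A", "B"), c(n1, n2)), sparse = TRUE)
  nm <- log_normalize(cm)
  res <- wilcoxon_rank_sum(nm)
  dense <- as.matrix(nm$values)
  for (g in seq_len(ng)) {
    x <- dense[g, seq_len(n1)]; y <- dense[g, n1 + seq_len(n2)]
    p_ref <- if (min(c(x, y)) == max(c(x, y))) 1 else
      suppressWarnings(stats::wilcox.test(y, x, exact = FALSE)$p.value)
    expect_equal(res$p_unadj[g], p_ref, tolerance = 1e-10)
  }

  # identical value multisets in both groups -> p = 1
  same <- make_norm(matrix(c(1, 2, 3, 1, 2, 3), 1), rep(c("A", "B"), each = 3))
  expect_equal(wilcoxon_rank_sum(same)$p_unadj, 1)
  # constant gene -> p = 1
  const <- make_norm(matrix(0, 1, 6), rep(c("A", "B"), each = 3))
  expect_equal(wilcoxon_rank_sum(const)$p_unadj, 1)
})

test_that("Wilcoxon type-I error is calibrated under an exchangeable null", {
  set.seed(41)
  ng <- 400; n <- 60
  m <- matrix(rpois(ng * 2 * n, 1.2), ng,
              dimnames = list(sprintf("g%03d", 1:ng), sprintf("c%03d", 1:(2 * n))))
  cm <- make_cm(m, group = rep(c("A", "B"), each = n), sparse = TRUE)
  res <- wilcoxon_rank_sum(log_normalize(cm))
  rate <- mean(res$p_unadj <= 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / ng)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("Wilcoxon log2fc uses the depth-normalized pseudocount-1 ratio and prefilters can disable genes", {
  m <- matrix(c(0, 10, 0, 10, 5, 5, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("c", 1:4)))
  cm <- make_cm(m, group = c("A", "A", "B", "B"))
  nm <- log_normalize(cm, scale_factor = 10)
  res <- wilcoxon_rank_sum(nm)
  mean_a <- mean(expm1(nm$values["g1", 1:2]))
  mean_b <- mean(expm1(nm$values["g1", 3:4]))
  expect_equal(res$log2fc[1], log2((mean_b + 1) / (mean_a + 1)))

  strict <- wilcoxon_rank_sum(nm, logfc_threshold = 10)
  expect_true(all(is.na(strict$p_unadj)))
  pct <- wilcoxon_rank_sum(nm, min_pct = 0.75)
  expect_true(is.na(pct$p_unadj[1]))     # g1 detected in 50% of each group
  expect_false(is.na(pct$p_unadj[2]))
})

test_that("adjusted p-values are ordered p_unadj <= p_bh <= p_bonf for both tests", {
  sim <- small_sim(seed = 8, n_genes = 150, n_cells = 90)
  for (res in list(nb_wald_test(sim$bulk),
                   wilcoxon_rank_sum(log_normalize(sim$sc)))) {
    ok <- !is.na(res$p_unadj)
    expect_true(all(res$p_unadj[ok] <= res$p_bh[ok] + 1e-12))
    expect_true(all(res$p_bh[ok] <= res$p_bonf[ok] + 1e-12))
    expect_equal(res$p_bonf[ok],
                 pmin(1, res$p_unadj[ok] * sum(ok)))
    # BH is monotone: ordering by p_bh never inverts ordering by p_unadj
    ord <- order(res$p_unadj[ok])
    expect_true(!is.unsorted(res$p_bh[ok][ord]))
  }
})
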