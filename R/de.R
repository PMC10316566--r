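# Differential-expression tests: a DESeq2-style negative-binomial Wald
# test on replicate-level (bulk or pseudo-bulk) counts, and a Wilcoxon
# rank-sum marker test on log-normalized single cells. Both return the
# same DEResult table layout:
#   gene_id, base_mean, log2fc, stat, p_unadj, p_bh, p_bonf, mean_tpm

de_result_table <- function(gene_id, base_mean, log2fc, stat, p_unadj,
                            mean_tpm = NA_real_) {
  data.frame(gene_id = gene_id,
             base_mean = base_mean,
             log2fc = log2fc,
             stat = stat,
             p_unadj = p_unadj,
             p_bh = adjust_pvalues(p_unadj, "BH"),
             p_bonf = adjust_pvalues(p_unadj, "bonferroni"),
             mean_tpm = mean_tpm,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-of-ratios size factors
#'
#' The normalization step of the NB Wald test: the reference profile is
#' the per-gene geometric mean over columns, computed over genes with
#' strictly positive counts in every column, and each column's size factor
#' is the median over those genes of `count / reference`.
#'
#' @param cm A [count_matrix()] (or bare counts matrix) with >= 2 columns.
#' @return Named numeric vector of positive size factors, one per column.
#' @export
size_factors_median_of_ratios <- function(cm) {
  counts <- if (inherits(cm, "CountMatrix")) cm$counts else cm
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 columns")
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene with positive counts in all columns: cannot normalize")
  sf <- apply(logc[use, , drop = FALSE], 2,
              function(lc) exp(stats::median(lc - loggeo[use])))
  stats::setNames(sf, colnames(counts))
}

# Vectorized per-gene, per-group NB rate MLE with known dispersions and
# offsets log(sf): Newton iterations on eta = log(q), concave in eta.
# Returns log-rate and the Fisher information sum(mu / (1 + alpha * mu)).
nb_group_mle <- function(counts, sf, alpha, tol = 1e-10, max_iter = 50L) {
  rs <- rowSums(counts)
  ssf <- sum(sf)
  # boundary: a group with zero total gets half a count so the Wald
  # statistic stays finite (documented conservative convention)
  rs_adj <- ifelse(rs == 0, 0.5, rs)
  eta <- log(rs_adj / ssf)
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf
    denom <- 1 + alpha * mu
    score <- rowSums((counts - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta <- eta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% sf
  list(eta = eta, info = rowSums(mu / (1 + alpha * mu)))
}

# Per-gene NB dispersion: method of moments on size-factor-normalized
# counts, with a parametric trend alpha(m) = a0 + a1/m fitted by a Gamma
# GLM to the stable gene-wise estimates. The dispersion used is
# max(gene-wise, trend), floored at `floor_at`: with few replicates a
# gene-wise estimate below the trend is treated as unstable
# (underestimated) and replaced by the trend, which keeps the Wald test's
# far tail calibrated without the shrinkage machinery of larger tools.
estimate_dispersions <- function(norm, design, sf, floor_at = 1e-8) {
  n <- ncol(norm)
  m <- rowMeans(norm)
  groups <- split(seq_len(n), design)
  ss <- 0
  for (j in groups) {
    sub <- norm[, j, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  v <- ss / (n - length(groups))
  xim <- mean(1 / sf)
  raw <- (v - xim * m) / m^2
  stable <- is.finite(raw) & raw > 0 & m > 0
  trend_fun <- fit_dispersion_trend(raw[stable], m[stable])
  disp <- pmax(ifelse(stable, raw, 0), trend_fun(m), floor_at)
  disp[!is.finite(disp)] <- floor_at
  disp
}

fit_dispersion_trend <- function(disps, means, min_genes = 10) {
  if (length(disps) < min_genes) {
    med <- if (length(disps)) stats::median(disps) else 0
    return(function(m) rep(med, length(m)))
  }
  # iterate the Gamma-family fit, trimming extreme ratios, as is standard
  # for parametric mean-dispersion trends
  keep <- rep(TRUE, length(disps))
  co <- c(stats::median(disps), 1)
  for (it in 1:10) {
    fit <- try(suppressWarnings(stats::glm(
      disps[keep] ~ I(1 / means[keep]),
      family = stats::Gamma(link = "identity"),
      start = co)), silent = TRUE)
    if (inherits(fit, "try-error")) break
    co_new <- pmax(stats::coef(fit), 0)
    pred <- co_new[1] + co_new[2] / means
    ratio <- disps / pmax(pred, 1e-12)
    keep_new <- ratio > 1e-4 & ratio < 15
    if (!any(keep_new) || !is.finite(sum(co_new))) break
    done <- sum(abs(co_new - co)) < 1e-6 * sum(abs(co) + 1e-12)
    co <- co_new
    keep <- keep_new
    if (done) break
  }
  function(m) pmax(co[1] + co[2] / m, 0)
}

#' Negative-binomial Wald test on replicate counts
#'
#' A self-contained DESeq2-style two-group test for bulk or pseudo-bulk
#' count tables: median-of-ratios size factors, per-gene NB dispersion by
#' method of moments stabilized with a fitted parametric mean-dispersion
#' trend, exact per-group NB rate MLEs with offset `log(size factor)`,
#' and a two-sided Wald test of the group log-ratio against zero.
#'
#' This is deliberately a documented simplification of the full DESeq2
#' procedure: no Cox–Reid dispersion shrinkage, no LFC shrinkage, no
#' independent filtering, no outlier handling. Results should be labelled
#' "NB Wald (DESeq2-style)", never "DESeq2".
#'
#' @param cm A [count_matrix()] of replicate-level counts, >= 2 columns
#'   per group.
#' @param groups Two-level factor (or character) of column conditions;
#'   defaults to the column group labels. The reported `log2fc` is second
#'   level vs first level.
#' @param mean_tpm Optional named per-gene abundance carried through to
#'   the `mean_tpm` column (used downstream for stratification).
#' @param dispersions Optional per-gene NB dispersions overriding the
#'   internal estimate (e.g. known simulation truth, or a near-zero value
#'   for a Poisson-limit analysis).
#' @return A `DEResult` data.frame (see [adjust_pvalues()] for the
#'   adjusted columns). Genes with all-zero counts get `NA` statistics
#'   and are excluded from the number of tests m of the adjustments.
#' @export
nb_wald_test <- function(cm, groups = NULL, mean_tpm = NULL,
                         dispersions = NULL) {
  counts <- as.matrix(cm$counts)
  if (is.null(groups)) groups <- cm$group
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2))
    stop("each group needs >= 2 columns: no replication")

  sf <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(norm)
  alpha <- if (is.null(dispersions)) estimate_dispersions(norm, groups, sf)
           else pmax(rep_len(dispersions, nrow(counts)), 1e-8)

  j1 <- which(groups == levels(groups)[1])
  j2 <- which(groups == levels(groups)[2])
  fit1 <- nb_group_mle(counts[, j1, drop = FALSE], sf[j1], alpha)
  fit2 <- nb_group_mle(counts[, j2, drop = FALSE], sf[j2], alpha)

  beta <- fit2$eta - fit1$eta
  se <- sqrt(1 / pmax(fit1$info, 1e-12) + 1 / pmax(fit2$info, 1e-12))
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))

  allzero <- rowSums(counts) == 0
  stat[allzero] <- NA_real_
  p[allzero] <- NA_real_
  beta[allzero] <- NA_real_

  mt <- if (is.null(mean_tpm)) NA_real_ else unname(mean_tpm[rownames(counts)])
  de_result_table(rownames(counts), base_mean, beta / log(2), stat, p, mt)
}

#' Wilcoxon rank-sum test per gene on log-normalized cells
#'
#' The marker-test path: a two-sided Wilcoxon rank-sum (Mann–Whitney)
#' test of each gene's log-normalized expression between the two cell
#' groups, using midranks for ties and the normal approximation with
#' tie-corrected variance and continuity correction (the default
#' large-sample path of standard implementations). Computation exploits
#' sparsity: zeros are handled as one tied block per gene.
#'
#' The reported `log2fc` is `log2((mean(expm1(x_B)) + 1) /
#' (mean(expm1(x_A)) + 1))`, i.e. a pseudocount of 1 on the
#' depth-normalized scale; `base_mean` is the mean normalized value over
#' all cells. Genes constant across all cells get p = 1.
#'
#' @param norm A [log_normalize()] result (or a `CountMatrix`-shaped list
#'   with `values`).
#' @param groups Two-level factor of cell groups; defaults to the stored
#'   group labels. log2fc is second level vs first.
#' @param logfc_threshold,min_pct Prefilters on minimum absolute log2fc
#'   and minimum detection fraction in either group; genes failing them
#'   get `NA` statistics (and drop out of m). Both default to 0, i.e.
#'   disabled, so every gene is tested.
#' @param mean_tpm Optional named per-gene abundance for the `mean_tpm`
#'   column.
#' @return A `DEResult` data.frame.
#' @export
wilcoxon_rank_sum <- function(norm, groups = NULL, logfc_threshold = 0,
                              min_pct = 0, mean_tpm = NULL) {
  v <- norm$values
  if (is.null(groups)) groups <- norm$group
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  is2 <- groups == levels(groups)[2]
  n1 <- sum(!is2); n2 <- sum(is2)
  if (n1 < 1 || n2 < 1) stop("each group needs >= 1 cell")
  ng <- nrow(v)

  sparse <- inherits(v, "sparseMatrix")
  if (sparse) {
    tv <- Matrix::t(methods::as(methods::as(v, "CsparseMatrix"), "dMatrix"))
    px <- tv@p; ix <- tv@i; xx <- tv@x
  }

  stat <- numeric(ng); p <- numeric(ng)
  pct1 <- numeric(ng); pct2 <- numeric(ng)
  sum_expm1_1 <- numeric(ng); sum_expm1_2 <- numeric(ng)
  mean_all <- numeric(ng)
  n <- n1 + n2
  r0 <- n1 * (n1 + 1) / 2
  for (g in seq_len(ng)) {
    if (sparse) {
      idx <- if (px[g + 1] > px[g]) (px[g] + 1):px[g + 1] else integer(0)
      cells <- ix[idx] + 1L
      vals <- xx[idx]
      in2 <- is2[cells]
    } else {
      row <- v[g, ]
      cells <- which(row != 0)
      vals <- row[cells]
      in2 <- is2[cells]
    }
    k1 <- sum(!in2); k2 <- length(vals) - k1
    z <- n - length(vals)                      # zeros, tied at the bottom
    pct1[g] <- k1 / n1; pct2[g] <- k2 / n2
    e <- expm1(vals)
    sum_expm1_1[g] <- sum(e[!in2]); sum_expm1_2[g] <- sum(e[in2])
    mean_all[g] <- sum(vals) / n

    if (length(vals) == 0 ||
        (length(vals) == n && min(vals) == max(vals))) {
      stat[g] <- 0; p[g] <- 1          # constant gene
      next
    }
    r <- z + rank(vals)                        # midranks above the zero block
    R1 <- (z1 <- n1 - k1) * (z + 1) / 2 + sum(r[!in2])
    U1 <- R1 - r0
    mu_u <- n1 * n2 / 2
    ties <- tabulate(match(vals, unique(vals)))
    tie_term <- sum(ties^3 - ties) + (z^3 - z)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) { stat[g] <- 0; p[g] <- 1; next }
    d <- U1 - mu_u
    zstat <- (d - sign(d) * 0.5) / sqrt(sigma2)
    stat[g] <- zstat
    p[g] <- min(1, 2 * stats::pnorm(-abs(zstat)))
  }

  log2fc <- log2((sum_expm1_2 / n2 + 1) / (sum_expm1_1 / n1 + 1))
  fail <- pmax(pct1, pct2) < min_pct | abs(log2fc) < logfc_threshold
  stat[fail] <- NA_real_; p[fail] <- NA_real_

  mt <- if (is.null(mean_tpm)) NA_real_ else unname(mean_tpm[rownames(v)])
  de_result_table(rownames(v), mean_all, log2fc, stat, p, mt)
}

#' Multiple-testing adjustment
#'
#' Benjamini–Hochberg step-up FDR adjustment or Bonferroni family-wise
#' correction, with `NA` p-values excluded from the number of tests m and
#' propagated. Backed by [stats::p.adjust()], whose NA handling matches
#' this contract.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Call the significant gene set from a DEResult table
#'
#' @param res A `DEResult` data.frame.
#' @param alpha Significance level; genes with adjusted p equal to or
#'   lower than `alpha` are called (inclusive threshold).
#' @param adjustment `"BH"` (column `p_bh`) or `"bonferroni"` (`p_bonf`).
#' @return Character vector of significant gene IDs.
#' @export
call_degs <- function(res, alpha = 0.05,
                      adjustment = c("BH", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  col <- if (adjustment == "BH") res$p_bh else res$p_bonf
  res$gene_id[!is.na(col) & col <= alpha]
}
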