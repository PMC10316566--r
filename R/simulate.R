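#' Configuration for the paired bulk / single-cell simulator
#'
#' Defines a two-cell-type experiment in which each of `n_replicates`
#' biological replicates (differentiation rounds) is split into one
#' single-cell library and one bulk RNA-seq library per type, so the two
#' modalities of a replicate share the same perturbed gene-level means.
#' Genes have a ground-truth relative abundance, negative-binomial
#' dispersion, and (for the DE fraction) a true log2 fold change of type B
#' over type A.
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_type Cells per cell type at the 100% level, split
#'   evenly over the replicate libraries (default 5000, i.e. roughly 1667
#'   cells per library).
#' @param n_replicates Replicate rounds; yields this many single-cell
#'   libraries and this many bulk samples per type (default 3).
#' @param frac_de Fraction of genes truly differentially expressed, in
#'   `[0, 1)`; exactly `round(frac_de * n_genes)` genes get a nonzero
#'   `true_log2fc`.
#' @param log2fc_distribution True effect-size distribution. Either
#'   `list(type = "mixture", prob_modest, modest_range, large_range)` —
#'   a random-sign mixture of modest (uniform on `modest_range`, default
#'   0.5–2) and large (uniform on `large_range`, default 2–6) effects —
#'   or `list(type = "fixed", values = ...)` recycling `values` (signed)
#'   over the DE genes in gene order.
#' @param baseline_mean_distribution `list(meanlog, sdlog)` of the
#'   log-normal gene relative-abundance distribution (arbitrary scale;
#'   normalized to proportions internally).
#' @param dispersion_model `list(asymptotic, extra, sdlog)`: the per-gene
#'   NB dispersion is `(asymptotic + extra / m) * e`, with `m` the expected
#'   per-cell count of the gene and `e` a mean-one log-normal noise with
#'   the given `sdlog` — the usual decreasing mean–dispersion trend with
#'   gene-level scatter.
#' @param cell_library_size_distribution `list(meanlog, sdlog)` of the
#'   log-normal per-cell total-count distribution (default median 8000
#'   counts, typical of 10x 3' v3.1 data).
#' @param bulk_depth Expected total counts per bulk replicate (default
#'   1.1e8, so thinning to a 1e8 reference level is always feasible).
#' @param bulk_dispersion Technical NB dispersion of bulk counts around the
#'   replicate means (small; biological replicate-to-replicate variation is
#'   carried by `replicate_noise_sd` instead).
#' @param replicate_noise_sd Log-scale (natural log) SD of the per-gene,
#'   per-replicate, per-type mean perturbation shared by the bulk and
#'   single-cell libraries of a replicate. Drawn mean-corrected so expected
#'   rates equal the ground-truth rates.
#' @param gene_length_distribution `list(meanlog, sdlog)` of simulated gene
#'   lengths in bases (floored at 100).
#' @param group_names Labels of the two cell types.
#' @param seed Integer root seed; identical config + seed gives
#'   byte-identical output.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_genes = 10000,
                              n_cells_per_type = 5000,
                              n_replicates = 3,
                              frac_de = 0.3,
                              log2fc_distribution = list(
                                type = "mixture", prob_modest = 0.5,
                                modest_range = c(0.5, 2),
                                large_range = c(2, 6)),
                              baseline_mean_distribution = list(
                                meanlog = 1, sdlog = 2),
                              dispersion_model = list(
                                asymptotic = 0.2, extra = 1, sdlog = 0.3),
                              cell_library_size_distribution = list(
                                meanlog = log(8000), sdlog = 0.35),
                              bulk_depth = 1.1e8,
                              bulk_dispersion = 0.005,
                              replicate_noise_sd = 0.1,
                              gene_length_distribution = list(
                                meanlog = log(2000), sdlog = 0.7),
                              group_names = c("typeA", "typeB"),
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "SimulationConfig")
  stopifnot(n_genes >= 1, n_cells_per_type >= 1, n_replicates >= 1,
            frac_de >= 0, frac_de < 1,
            bulk_depth >= 1, bulk_dispersion > 0,
            replicate_noise_sd >= 0,
            length(group_names) == 2, !anyDuplicated(group_names))
  if (!log2fc_distribution$type %in% c("mixture", "fixed"))
    stop("log2fc_distribution$type must be 'mixture' or 'fixed'")
  if (exp(cell_library_size_distribution$meanlog) < 1)
    stop("degenerate simulation: expected per-cell total below one count")
  cfg
}

draw_true_log2fc <- function(n_de, dist) {
  if (n_de == 0) return(numeric(0))
  if (dist$type == "fixed") return(rep_len(dist$values, n_de))
  mag <- ifelse(stats::runif(n_de) < dist$prob_modest,
                stats::runif(n_de, dist$modest_range[1], dist$modest_range[2]),
                stats::runif(n_de, dist$large_range[1], dist$large_range[2]))
  mag * sample(c(-1, 1), n_de, replace = TRUE)
}

# Mean-one multiplicative log-normal noise
lognoise <- function(n, sdlog) exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))

#' Simulate a paired bulk and single-cell experiment with known truth
#'
#' Draws gene-level ground truth from `config`, then for every replicate
#' and cell type generates (i) one sparse single-cell library of NB counts
#' with per-cell library sizes and (ii) one bulk sample of NB counts at
#' `bulk_depth`, both around the same log-normally perturbed per-replicate
#' gene means — so bulk and single-cell data of a replicate share their
#' biological signal, as when one cell harvest is split across assays.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   * `sc`: sparse [count_matrix()] of all cells (groups = cell types,
#'     libraries = `<type>_r<replicate>`),
#'   * `bulk`: dense [count_matrix()] of `2 * n_replicates` bulk samples,
#'   * `truth`: data.frame with `gene_id`, `base_mean` (expected type-A
#'     count per bulk replicate), `true_log2fc`, `dispersion`, `is_de`,
#'   * `lengths`: named gene-length vector (bases),
#'   * `config`: the config used.
#' @export
simulate_paired_experiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  ng <- config$n_genes
  gene_ids <- sprintf("g%0*d", nchar(ng), seq_len(ng))

  gp <- local_seed(derive_seed(config$seed, "gene-params"), {
    rel <- stats::rlnorm(ng, config$baseline_mean_distribution$meanlog,
                         config$baseline_mean_distribution$sdlog)
    n_de <- round(config$frac_de * ng)
    de_idx <- sort(sample.int(ng, n_de))
    lfc <- numeric(ng)
    lfc[de_idx] <- draw_true_log2fc(n_de, config$log2fc_distribution)
    lbar <- exp(config$cell_library_size_distribution$meanlog +
                  config$cell_library_size_distribution$sdlog^2 / 2)
    m_cell <- rel / sum(rel) * lbar
    disp <- (config$dispersion_model$asymptotic +
               config$dispersion_model$extra / m_cell) *
      lognoise(ng, config$dispersion_model$sdlog)
    len <- pmax(100, round(stats::rlnorm(
      ng, config$gene_length_distribution$meanlog,
      config$gene_length_distribution$sdlog)))
    list(rel = rel, lfc = lfc, disp = disp, len = len)
  })

  rate <- cbind(gp$rel, gp$rel * 2^gp$lfc)  # type A, type B
  colnames(rate) <- config$group_names
  truth <- data.frame(
    gene_id = gene_ids,
    base_mean = config$bulk_depth * gp$rel / sum(gp$rel),
    true_log2fc = gp$lfc,
    dispersion = gp$disp,
    is_de = gp$lfc != 0,
    stringsAsFactors = FALSE)

  n_rep <- config$n_replicates
  cells_per_lib <- diff(round(seq(0, config$n_cells_per_type,
                                  length.out = n_rep + 1)))
  sc_libs <- list()
  bulk_cols <- matrix(0L, ng, 2 * n_rep)
  bulk_ids <- character(2 * n_rep)
  bulk_group <- character(2 * n_rep)
  # replicate (differentiation-round) effects are shared by the two cell
  # types and both assays of a round: one cell harvest feeds all of them
  rep_noise <- lapply(seq_len(n_rep), function(r)
    local_seed(derive_seed(config$seed, "repnoise", r),
               lognoise(ng, config$replicate_noise_sd)))
  k <- 0
  for (t in 1:2) {
    type <- config$group_names[t]
    for (r in seq_len(n_rep)) {
      q <- rate[, t] * rep_noise[[r]]
      pi_r <- q / sum(q)
      lib_id <- sprintf("%s_r%d", type, r)

      bulk_counts <- local_seed(
        derive_seed(config$seed, "bulk", type, r),
        stats::rnbinom(ng, mu = config$bulk_depth * pi_r,
                       size = 1 / config$bulk_dispersion))
      k <- k + 1
      bulk_cols[, k] <- bulk_counts
      bulk_ids[k] <- sprintf("%s_bulk_r%d", type, r)
      bulk_group[k] <- type

      sc_libs[[lib_id]] <- local_seed(
        derive_seed(config$seed, "sc", type, r),
        simulate_sc_library(pi_r, gp$disp, cells_per_lib[r],
                            config$cell_library_size_distribution,
                            gene_ids, lib_id))
    }
  }

  sc_counts <- do.call(cbind, unname(sc_libs))
  sc_lib_lab <- rep(names(sc_libs), vapply(sc_libs, ncol, 0L))
  sc_group <- sub("_r\\d+$", "", sc_lib_lab)
  dimnames(bulk_cols) <- list(gene_ids, bulk_ids)

  list(sc = count_matrix(sc_counts, group = sc_group, library = sc_lib_lab),
       bulk = count_matrix(bulk_cols, group = bulk_group, library = bulk_ids),
       truth = truth,
       lengths = stats::setNames(as.numeric(gp$len), gene_ids),
       config = config)
}

# One sparse single-cell library: NB counts with per-cell expected totals
# drawn log-normal and per-gene dispersions `disp`. Drawn in cell chunks to
# bound dense memory; assembled as one sparseMatrix call.
simulate_sc_library <- function(pi_r, disp, n_cells, libsize_dist,
                                gene_ids, lib_id) {
  ng <- length(pi_r)
  L <- stats::rlnorm(n_cells, libsize_dist$meanlog, libsize_dist$sdlog)
  chunk <- max(1L, min(n_cells, floor(4e6 / ng)))
  starts <- seq(1L, n_cells, by = chunk)
  ii <- vector("list", length(starts)); jj <- ii; xx <- ii
  size_g <- 1 / disp
  for (s in seq_along(starts)) {
    cols <- starts[s]:min(starts[s] + chunk - 1L, n_cells)
    mu <- outer(pi_r, L[cols])
    x <- stats::rnbinom(length(mu), mu = mu, size = size_g)
    nz <- which(x > 0)
    ii[[s]] <- ((nz - 1L) %% ng) + 1L
    jj[[s]] <- ((nz - 1L) %/% ng) + cols[1L]
    xx[[s]] <- x[nz]
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(ng, n_cells),
    dimnames = list(gene_ids,
                    sprintf("%s_c%0*d", lib_id, nchar(n_cells),
                            seq_len(n_cells))))
}

#' Quartile labels of the reference DEGs, by three stratifiers
#'
#' Restricts to the reference DEG set (BH-adjusted p <= `alpha` in
#' `bulk_de`) and assigns each of those genes to a quartile Q1–Q4 three
#' ways: by unadjusted p-value ascending (Q1 = smallest p), by absolute
#' log2 fold change descending (Q1 = largest effect), and by transcript
#' abundance (`mean_tpm`) descending (Q1 = most abundant). Ties break by
#' ascending gene ID so reports are deterministic.
#'
#' @param truth Ground-truth table from [simulate_paired_experiment()]
#'   (only its gene universe is used).
#' @param bulk_de `DEResult` table of the bulk reference analysis; must
#'   cover all genes in `truth` and carry a `mean_tpm` column.
#' @param alpha Significance level for the reference DEG set.
#' @return data.frame with `gene_id` and factor columns `q_p`, `q_lfc`,
#'   `q_tpm` (levels `Q1`–`Q4`), one row per reference DEG.
#' @export
truth_quartiles <- function(truth, bulk_de, alpha = 0.05) {
  if (!all(truth$gene_id %in% bulk_de$gene_id))
    stop("bulk_de must cover all genes in truth")
  de <- bulk_de[bulk_de$gene_id %in% truth$gene_id, , drop = FALSE]
  ref <- de[!is.na(de$p_bh) & de$p_bh <= alpha, , drop = FALSE]
  if (nrow(ref) < 4) stop("fewer than 4 reference DEGs: cannot form quartiles")
  data.frame(
    gene_id = ref$gene_id,
    q_p = assign_quartiles(ref$p_unadj, ref$gene_id, decreasing = FALSE),
    q_lfc = assign_quartiles(abs(ref$log2fc), ref$gene_id, decreasing = TRUE),
    q_tpm = assign_quartiles(ref$mean_tpm, ref$gene_id, decreasing = TRUE),
    stringsAsFactors = FALSE)
}

# Quartile labels by a sort key with deterministic gene-ID tie-break.
# Q1 holds the first quarter in sort order (key ascending unless
# decreasing = TRUE).
assign_quartiles <- function(key, ids, decreasing = FALSE) {
  n <- length(key)
  if (n < 4) stop("need at least 4 values to form quartiles")
  ord <- order(if (decreasing) -key else key, ids)
  q <- integer(n)
  q[ord] <- ceiling(seq_len(n) * 4 / n)
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}
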