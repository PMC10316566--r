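#' Sampling plan for the two down-sampling axes
#'
#' Describes the evaluation grid: the cell fractions at which the
#' single-cell data are repeatedly subsampled (default 100% down to 1%,
#' i.e. roughly 5,000 down to 50 cells per type at the default simulated
#' size), the number of random repeats per level below 100%, and the
#' target read totals for bulk depth thinning (default 100M down to 5M
#' read pairs; the first, largest level acts as the reference).
#'
#' @param cell_fractions Fractions in `(0, 1]`, sorted descending, unique.
#' @param n_repeats Random repeats per fraction (default 3); the 100%
#'   level is deterministic and all its repeats are identical.
#' @param read_depths Target per-sample read totals, sorted descending.
#' @param seed Integer root seed for all subsampling randomness; child
#'   seeds are derived per (fraction, repeat, library) with
#'   [derive_seed()], so extending the grid never perturbs existing draws.
#' @return A list of class `SamplingPlan`.
#' @export
sampling_plan <- function(cell_fractions = c(1, 0.8, 0.6, 0.4, 0.2,
                                             0.1, 0.05, 0.02, 0.01),
                          n_repeats = 3,
                          read_depths = c(100e6, 40e6, 20e6, 10e6, 5e6),
                          seed = 1L) {
  stopifnot(all(cell_fractions > 0), all(cell_fractions <= 1),
            !is.unsorted(rev(cell_fractions), strictly = TRUE),
            n_repeats >= 1,
            length(read_depths) == 0 ||
              !is.unsorted(rev(read_depths), strictly = TRUE))
  structure(list(cell_fractions = cell_fractions,
                 n_repeats = as.integer(n_repeats),
                 read_depths = read_depths,
                 seed = as.integer(seed)),
            class = "SamplingPlan")
}

#' Randomly subsample cells, stratified by replicate library
#'
#' Draws `round(fraction * n_cells)` cells without replacement from each
#' library independently; a sampled cell's counts are never altered and
#' the gene set is unchanged. Fraction 1 returns the input exactly (no
#' randomness). The draw depends only on
#' `(seed, fraction, repeat_index, library)`.
#'
#' @param cm A [count_matrix()] of cells.
#' @param fraction Fraction in `(0, 1]`.
#' @param repeat_index Which random repeat this is (1-based).
#' @param seed Root seed (e.g. the plan's).
#' @return A `CountMatrix` with the sampled cells, in original column
#'   order. Errors if the fraction rounds to zero cells in any library.
#' @export
subsample_cells <- function(cm, fraction, repeat_index = 1L, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(cm)
  keep <- logical(ncol(cm$counts))
  for (lib in unique(cm$library)) {
    j <- which(cm$library == lib)
    n_keep <- round(fraction * length(j))
    if (n_keep == 0)
      stop(sprintf("fraction %g rounds to zero cells in library %s",
                   fraction, lib))
    pick <- local_seed(derive_seed(seed, "cells", fraction, repeat_index, lib),
                       sample(j, n_keep))
    keep[pick] <- TRUE
  }
  cm_subset_cols(cm, keep)
}

#' Thin counts to a target sequencing depth
#'
#' Emulates without-replacement read subsampling at the count level: per
#' column, `target_total` reads are drawn without replacement from the
#' column's reads, so the thinned gene counts follow the multivariate
#' hypergeometric distribution and the column total equals `target_total`
#' exactly. Columns already at the target are returned unchanged.
#'
#' @param cm A [count_matrix()].
#' @param target_total Target total per column; must not exceed any
#'   column's current total.
#' @param seed Root seed; the draw for a column depends only on
#'   `(seed, target_total, column_id)`.
#' @return A `CountMatrix` of the same shape with thinned integer counts.
#' @export
thin_reads <- function(cm, target_total, seed = 1L) {
  counts <- as.matrix(cm$counts)
  tot <- colSums(counts)
  if (any(tot < target_total))
    stop(sprintf("target %g exceeds the total of column %s",
                 target_total, colnames(counts)[which.min(tot)]))
  out <- counts
  for (j in seq_len(ncol(counts))) {
    if (tot[j] == target_total) next
    out[, j] <- local_seed(
      derive_seed(seed, "thin", target_total, colnames(counts)[j]),
      rmvhyper(counts[, j], target_total))
  }
  count_matrix(out, group = cm$group, library = cm$library)
}

# Multivariate hypergeometric draw by sequential conditioning: gene g's
# count given the previous draws is univariate hypergeometric.
rmvhyper <- function(counts, k) {
  out <- numeric(length(counts))
  remaining <- sum(counts)
  left <- k
  for (g in which(counts > 0)) {
    if (left == 0) break
    x <- stats::rhyper(1, counts[g], remaining - counts[g], left)
    out[g] <- x
    left <- left - x
    remaining <- remaining - counts[g]
  }
  out
}
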