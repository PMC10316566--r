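#' Cell filtering parameters
#'
#' Cells are retained when their number of detected genes (genes with
#' count > 0) lies within the inclusive bounds; the defaults reproduce the
#' common 200–5,000 detected-gene window for 10x 3' data.
#'
#' @param min_genes_detected Lower inclusive bound (default 200).
#' @param max_genes_detected Upper inclusive bound (default 5000).
#' @return A list of class `CellFilterParams`.
#' @export
cell_filter_params <- function(min_genes_detected = 200,
                               max_genes_detected = 5000) {
  stopifnot(min_genes_detected >= 0,
            min_genes_detected < max_genes_detected)
  structure(list(min_genes_detected = min_genes_detected,
                 max_genes_detected = max_genes_detected),
            class = "CellFilterParams")
}

#' Filter cells by number of detected genes
#'
#' @param cm A [count_matrix()] of cells.
#' @param params A [cell_filter_params()].
#' @return The `CountMatrix` restricted to the cells whose detected-gene
#'   count lies in `[min_genes_detected, max_genes_detected]` (inclusive);
#'   the gene set is unchanged. Errors if no cell survives.
#' @export
filter_cells <- function(cm, params = cell_filter_params()) {
  stopifnot(inherits(params, "CellFilterParams"), ncol(cm$counts) >= 1)
  detected <- Matrix::colSums(cm$counts > 0)
  keep <- detected >= params$min_genes_detected &
    detected <= params$max_genes_detected
  if (!any(keep)) stop("cell filter removed all cells: empty library")
  cm_subset_cols(cm, keep)
}

#' Aggregate cells into pseudo-bulk samples
#'
#' Sums each gene's counts over all member cells of a group, producing one
#' integer column per group label. The default grouping is cell type x
#' replicate library, which mirrors a bulk design with one sample per
#' replicate.
#'
#' @param cm A [count_matrix()] of cells.
#' @param group_by Character vector, one label per column; defaults to
#'   `paste(group, library)` collapsed to the library label when libraries
#'   are nested in groups.
#' @return A dense [count_matrix()] with one column per label (in first-
#'   appearance order); total counts are conserved per label.
#' @export
pseudo_bulk <- function(cm, group_by = NULL) {
  if (ncol(cm$counts) == 0) stop("empty input")
  if (is.null(group_by)) group_by <- cm$library
  stopifnot(length(group_by) == ncol(cm$counts))
  f <- factor(group_by, levels = unique(group_by))
  agg <- as.matrix(cm$counts %*%
                     Matrix::t(Matrix::fac2sparse(f, drop.unused.levels = FALSE)))
  storage.mode(agg) <- "double"
  colnames(agg) <- levels(f)
  grp <- vapply(levels(f), function(l) {
    g <- unique(cm$group[group_by == l])
    if (length(g) == 1) g else NA_character_
  }, "")
  count_matrix(agg, group = grp, library = levels(f))
}

#' Transcripts per million
#'
#' Length-normalized abundance: per column, `rate_g = count_g /
#' length_kb_g` and `TPM_g = rate_g / sum(rate) * 1e6`, so every column
#' sums to one million.
#'
#' @param cm A [count_matrix()].
#' @param lengths Named numeric vector of gene lengths in bases, covering
#'   every gene of `cm`.
#' @return A dense numeric matrix of TPM values (genes x columns).
#' @export
tpm <- function(cm, lengths) {
  genes <- rownames(cm$counts)
  if (!all(genes %in% names(lengths)))
    stop("gene lengths must cover all genes")
  len_kb <- lengths[genes] / 1000
  rate <- as.matrix(cm$counts) / len_kb
  tot <- colSums(rate)
  if (any(tot == 0)) stop("column of all zeros: TPM undefined")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Per-cell depth normalization with log transform
#'
#' The "LogNormalize" scheme: each count is divided by its cell's total,
#' multiplied by `scale_factor`, and transformed with the natural
#' `log1p`, i.e. `value = ln(1 + scale_factor * count / cell_total)`.
#' Zero counts map to zero, so sparsity is preserved.
#'
#' @param cm A [count_matrix()] of cells; every cell must have a positive
#'   total count.
#' @param scale_factor Pseudo-depth all cells are scaled to (default 1e4).
#' @return A list of class `NormalizedMatrix` with elements `values`
#'   (same storage class as the input counts), `group` and `library`.
#' @export
log_normalize <- function(cm, scale_factor = 1e4) {
  tot <- cm_col_totals(cm)
  if (any(tot == 0)) stop("cell with zero total count")
  if (inherits(cm$counts, "sparseMatrix")) {
    v <- methods::as(methods::as(cm$counts, "CsparseMatrix"), "dMatrix")
    percol <- rep.int(seq_len(ncol(v)), diff(v@p))
    v@x <- log1p(scale_factor * v@x / tot[percol])
  } else {
    v <- log1p(scale_factor * sweep(cm$counts, 2, tot, "/"))
  }
  structure(list(values = v, group = cm$group, library = cm$library),
            class = "NormalizedMatrix")
}
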