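#' Gene-by-column count matrix with column annotations
#'
#' The shared data container of the pipeline: an integer count matrix with
#' genes as rows and cells or bulk samples as columns, plus one group label
#' (cell type / condition) and one library label (replicate library of
#' origin) per column. Counts may be stored dense (`matrix`) or sparse
#' (`Matrix::dgCMatrix`); single-cell data should use the sparse form.
#'
#' @param counts Integer matrix (base `matrix` or sparse `Matrix`), genes x
#'   columns, non-negative whole numbers. Must carry rownames (gene IDs) and
#'   colnames (cell barcodes or sample names) unless `gene_ids` /
#'   `col_ids` are given.
#' @param group Character vector, one group label per column.
#' @param library Character vector, one replicate-library label per column.
#'   Defaults to a single library `"lib1"`.
#' @param gene_ids,col_ids Optional identifiers overriding the dimnames.
#'
#' @return An object of class `CountMatrix`: a list with elements `counts`,
#'   `group` (named character) and `library` (named character).
#' @examples
#' m <- matrix(c(3L, 0L, 0L, 5L), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' cm <- count_matrix(m, group = c("A", "B"))
#' dim(cm)
#' @export
count_matrix <- function(counts, group, library = NULL,
                         gene_ids = NULL, col_ids = NULL) {
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(col_ids)) colnames(counts) <- col_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene IDs as rownames and column IDs as colnames")
  if (is.null(library)) library <- rep("lib1", ncol(counts))
  if (length(group) != ncol(counts) || length(library) != ncol(counts))
    stop("group and library must have exactly one label per column")
  obj <- structure(
    list(counts = counts,
         group = stats::setNames(as.character(group), colnames(counts)),
         library = stats::setNames(as.character(library), colnames(counts))),
    class = "CountMatrix")
  validate_count_matrix(obj)
  obj
}

validate_count_matrix <- function(cm) {
  stopifnot(inherits(cm, "CountMatrix"))
  counts <- cm$counts
  if (anyDuplicated(rownames(counts)))
    stop("gene identifiers must be unique")
  if (anyDuplicated(colnames(counts)))
    stop("column identifiers must be unique")
  if (length(cm$group) != ncol(counts) || length(cm$library) != ncol(counts))
    stop("group and library must have exactly one label per column")
  x <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  if (length(x) && (min(x) < 0 || any(x != round(x))))
    stop("counts must be non-negative integers")
  invisible(cm)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
dimnames.CountMatrix <- function(x) dimnames(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d columns (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (inherits(x$counts, "sparseMatrix")) "sparse" else "dense"))
  cat("groups:   ", paste(sprintf("%s (%d)", names(table(x$group)),
                                  table(x$group)), collapse = ", "), "\n")
  cat("libraries:", paste(unique(x$library), collapse = ", "), "\n")
  invisible(x)
}

#' Subset the columns of a CountMatrix
#'
#' @param cm A [count_matrix()].
#' @param j Column index (integer, logical or character).
#' @return A `CountMatrix` with the selected columns; gene set unchanged.
#' @export
cm_subset_cols <- function(cm, j) {
  count_matrix(cm$counts[, j, drop = FALSE],
               group = cm$group[j], library = cm$library[j])
}

#' Combine CountMatrix objects column-wise
#'
#' All inputs must share an identical gene set (same order).
#' @param ... `CountMatrix` objects.
#' @return A single `CountMatrix`.
#' @export
cm_cbind <- function(...) {
  cms <- list(...)
  g <- rownames(cms[[1]]$counts)
  for (cm in cms) stopifnot(identical(rownames(cm$counts), g))
  count_matrix(do.call(cbind, lapply(cms, `[[`, "counts")),
               group = unlist(lapply(cms, `[[`, "group")),
               library = unlist(lapply(cms, `[[`, "library")))
}

#' Per-column total counts
#' @param cm A [count_matrix()].
#' @return Named numeric vector of column sums.
#' @export
cm_col_totals <- function(cm) {
  stats::setNames(Matrix::colSums(cm$counts), colnames(cm$counts))
}
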