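#' Read a 10x-style MTX triplet into a CountMatrix
#'
#' Reads a MatrixMarket sparse count matrix together with its feature and
#' barcode sidecar files (Cell Ranger layout). On disk the 10x convention
#' stores features as rows; the returned object always presents genes as
#' rows, detected from the feature/barcode line counts regardless of the
#' on-disk orientation. Duplicate feature IDs are disambiguated with
#' `make.unique()` (suffixes `.1`, `.2`, ...).
#'
#' @param matrix_path Path to the `.mtx` file (optionally gzipped).
#' @param features_path Path to the features/genes file: one feature per
#'   line; if tab-separated, the first field is used as the gene ID.
#' @param barcodes_path Path to the barcodes file, one barcode per line.
#' @param group,library Optional per-cell labels (recycled if length 1).
#' @return A [count_matrix()].
#' @export
read_10x_mtx <- function(matrix_path, features_path, barcodes_path,
                         group = "unknown", library = "lib1") {
  m <- read_mm(matrix_path)
  feats <- readLines(features_path)
  feats <- vapply(strsplit(feats, "\t", fixed = TRUE), `[`, "", 1L)
  bcs <- readLines(barcodes_path)
  if (nrow(m) == length(feats) && ncol(m) == length(bcs)) {
    # features-as-rows (10x convention)
  } else if (nrow(m) == length(bcs) && ncol(m) == length(feats)) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "matrix dimensions %d x %d match neither %d features x %d barcodes nor its transpose",
      nrow(m), ncol(m), length(feats), length(bcs)))
  }
  if (length(m@x) && any(m@x != round(m@x)))
    stop("matrix file contains non-integer entries")
  rownames(m) <- make.unique(feats, sep = ".")
  colnames(m) <- bcs
  count_matrix(m,
               group = rep_len(group, ncol(m)),
               library = rep_len(library, ncol(m)))
}

read_mm <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  m <- Matrix::readMM(con)
  methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
}

#' Write a CountMatrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` and `barcodes.tsv` into `dir`. If
#' `split_by_library = TRUE`, one subdirectory per replicate library is
#' written instead, each holding the triplet for that library's cells.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @param split_by_library Write one triplet per library label?
#' @return Invisibly, the director(y/ies) written.
#' @export
write_10x_mtx <- function(cm, dir, split_by_library = FALSE) {
  if (split_by_library) {
    dirs <- character(0)
    for (lib in unique(cm$library)) {
      sub <- file.path(dir, lib)
      write_10x_mtx(cm_subset_cols(cm, cm$library == lib), sub)
      dirs <- c(dirs, sub)
    }
    return(invisible(dirs))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(cm$counts, "CsparseMatrix"), "dMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read / write gene-by-sample count tables as TSV
#'
#' The table layout is a header row of sample names, gene IDs in the first
#' column (named `gene_id`), and an integer count body. Reading rejects
#' negative or fractional entries; a write followed by a read is lossless
#' (gene and sample order preserved).
#'
#' @param path File path.
#' @param group,library Optional per-sample labels (recycled if length 1).
#' @return `read_counts_tsv()` returns a [count_matrix()];
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path, group = "unknown", library = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("count table needs a gene column and >= 1 sample")
  genes <- df[[1]]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) stop("non-numeric entries in count table")
  if (any(num < 0) || any(num != round(num)))
    stop("counts must be non-negative integers")
  dimnames(num) <- list(genes, colnames(df)[-1])
  if (is.null(library)) library <- colnames(num)
  count_matrix(num,
               group = rep_len(group, ncol(num)),
               library = rep_len(library, ncol(num)))
}

#' @rdname read_counts_tsv
#' @param cm A [count_matrix()] to write.
#' @export
write_counts_tsv <- function(cm, path) {
  m <- as.matrix(cm$counts)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-length table
#'
#' Two tab-separated columns, `gene_id` and `length` (bases, >= 1). Lengths
#' are used for TPM; the table must cover every gene it is applied to.
#'
#' @param path File path.
#' @return `read_gene_lengths()` returns a named numeric vector.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  len <- as.numeric(df[[2]])
  if (anyNA(len) || any(len < 1)) stop("gene lengths must be >= 1")
  stats::setNames(len, as.character(df[[1]]))
}

#' @rdname read_gene_lengths
#' @param lengths Named numeric vector of gene lengths.
#' @export
write_gene_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length = as.integer(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the simulator's ground-truth table as TSV
#' @param path File path.
#' @return `read_truth_tsv()` returns the ground-truth `data.frame`.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  df$is_de <- as.logical(df$is_de)
  df
}

#' @rdname read_truth_tsv
#' @param truth Ground-truth `data.frame` from [simulate_paired_experiment()].
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect two CountMatrix objects on shared gene IDs
#'
#' Gene matching is by exact ID string; genes present in only one input are
#' dropped, and the number dropped from each side is reported via `message()`
#' so losses are visible rather than silent.
#'
#' @param a,b [count_matrix()] objects.
#' @return A list with elements `a` and `b` restricted to the shared genes,
#'   in the gene order of `a`.
#' @export
match_genes <- function(a, b) {
  shared <- intersect(rownames(a$counts), rownames(b$counts))
  da <- nrow(a$counts) - length(shared)
  db <- nrow(b$counts) - length(shared)
  if (da + db > 0)
    message(sprintf("match_genes: dropped %d genes from a, %d from b; %d shared",
                    da, db, length(shared)))
  if (!length(shared)) stop("no shared genes")
  list(a = count_matrix(a$counts[shared, , drop = FALSE], a$group, a$library),
       b = count_matrix(b$counts[shared, , drop = FALSE], b$group, b$library))
}
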