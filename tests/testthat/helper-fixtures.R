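# Small fixtures built in code.

make_cm <- function(m, group = NULL, library = NULL, sparse = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%02d", seq_len(ncol(m)))
  if (is.null(group)) group <- rep("A", ncol(m))
  if (sparse) m <- Matrix::Matrix(m, sparse = TRUE)
  count_matrix(m, group = group, library = library)
}

# A normalized-matrix object from explicit values (bypassing counts), for
# direct Wilcoxon checks.
make_norm <- function(values, group) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  structure(list(values = values,
                 group = stats::setNames(group, colnames(values)),
                 library = stats::setNames(rep("lib1", ncol(values)),
                                           colnames(values))),
            class = "NormalizedMatrix")
}

# Small paired simulation shared by several files.
small_sim <- function(seed = 42, n_genes = 400, n_cells = 240,
                      frac_de = 0.25, bulk_depth = 1e6, ...) {
  simulate_paired_experiment(simulation_config(
    n_genes = n_genes, n_cells_per_type = n_cells, frac_de = frac_de,
    bulk_depth = bulk_depth, seed = seed, ...))
}
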