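#' Write a dataset to an MTX + TSV directory
#'
#' Stores raw counts in MatrixMarket format as genes x cells (the 10x
#' convention; transposed back on load), gene ids in `genes.tsv`, cell ids
#' and labels in `cells.tsv`, and — when a `planted_truth` is supplied — the
#' marker map in `truth.json`.
#'
#' @param mat a raw-view [cell_matrix()] or an `sc_dataset` (its counts view
#'   is written).
#' @param dir output directory, created if missing.
#' @param truth optional `planted_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(mat, dir, truth = NULL) {
  if (inherits(mat, "sc_dataset")) {
    truth <- truth %||% mat$truth
    mat <- mat$counts
  }
  stopifnot(inherits(mat, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(mat$values), sparse = TRUE)  # genes x cells
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene_id = mat$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(cell_id = mat$cell_ids,
                                label = as.character(mat$labels)),
                     file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(marker_map = truth$marker_map,
           program_genes = truth$program_genes,
           dominant_type = truth$dominant_type),
      file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' Load a labeled expression matrix from an MTX + TSV directory
#'
#' Inverse of [write_dataset()]: reads the genes x cells MatrixMarket file,
#' transposes to cells x genes, and attaches ids and labels. Round-trip
#' save -> load is the identity on values, ids and labels.
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`;
#'   alternatively give the three paths explicitly.
#' @param matrix_path,genes_path,cells_path explicit file paths (override
#'   `dir`).
#' @return A raw-view [cell_matrix()].
#' @export
load_matrix <- function(dir = NULL, matrix_path = NULL, genes_path = NULL,
                        cells_path = NULL) {
  matrix_path <- matrix_path %||% file.path(dir, "matrix.mtx")
  genes_path <- genes_path %||% file.path(dir, "genes.tsv")
  cells_path <- cells_path %||% file.path(dir, "cells.tsv")
  for (p in c(matrix_path, genes_path, cells_path))
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  m <- Matrix::readMM(matrix_path)  # genes x cells
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character")
  cells <- utils::read.table(cells_path, sep = "\t", header = FALSE,
                             colClasses = "character", fill = TRUE,
                             na.strings = NULL)
  if (nrow(genes) != nrow(m))
    stop(sprintf("dimension mismatch: matrix has %d genes but genes.tsv has %d",
                 nrow(m), nrow(genes)), call. = FALSE)
  if (nrow(cells) != ncol(m))
    stop(sprintf("dimension mismatch: matrix has %d cells but cells.tsv has %d",
                 ncol(m), nrow(cells)), call. = FALSE)
  if (ncol(cells) < 2) cells$V2 <- ""
  cell_matrix(as.matrix(Matrix::t(m)), cells[[1]], genes[[1]], cells[[2]],
              view = "raw")
}

#' Read a planted-truth JSON written by [write_dataset()]
#' @param dir dataset directory containing `truth.json`.
#' @return A `planted_truth` list.
#' @export
read_truth <- function(dir) {
  p <- file.path(dir, "truth.json")
  if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                            call. = FALSE)
  x <- jsonlite::read_json(p, simplifyVector = TRUE)
  structure(list(marker_map = as.list(x$marker_map),
                 program_genes = x$program_genes,
                 dominant_type = x$dominant_type),
            class = "planted_truth")
}

#' Per-type decile expression summary
#'
#' For each cell type, genes are ranked by their mean expression within that
#' type (descending, ties broken by gene id) and split into 10 contiguous
#' bins of equal size (when `n_genes` is not divisible by 10 the earliest
#' bins receive one extra gene). The summary reports each bin's mean and its
#' share of the type's total expression; the size-weighted sum of bin means
#' recovers the type's overall mean exactly.
#'
#' @param mat a [cell_matrix()]; shares of total expression are most
#'   interpretable on the raw counts view.
#' @param n_bins number of bins (default 10, i.e. deciles).
#' @return A data.frame with columns `cell_type`, `decile` (1 = highest
#'   expression), `n_genes`, `mean_expression`, `share`.
#' @export
decile_expression_summary <- function(mat, n_bins = 10) {
  stopifnot(inherits(mat, "cell_matrix"))
  p <- ncol(mat$values)
  if (p < n_bins)
    stop(sprintf("need at least %d genes for a %d-bin summary, found %d",
                 n_bins, n_bins, p), call. = FALSE)
  sizes <- rep(p %/% n_bins, n_bins)
  extra <- p %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of <- rep(seq_len(n_bins), sizes)
  types <- levels(mat$labels)
  out <- lapply(types, function(ty) {
    gm <- colMeans(mat$values[mat$labels == ty, , drop = FALSE])
    ord <- order_desc_then_id(gm, mat$gene_ids)
    ranked <- gm[ord]
    total <- sum(ranked)
    data.frame(
      cell_type = ty, decile = seq_len(n_bins), n_genes = sizes,
      mean_expression = as.numeric(tapply(ranked, bin_of, mean)),
      share = if (total > 0) as.numeric(tapply(ranked, bin_of, sum)) / total
              else rep(NA_real_, n_bins))
  })
  do.call(rbind, out)
}
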