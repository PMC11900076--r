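#' Labeled expression matrix
#'
#' The central container of the package: a dense cells x genes matrix of
#' non-negative expression values together with per-cell type labels and a
#' `view` tag recording whether the values are raw counts or log1p-CPM.
#'
#' @param values numeric cells x genes matrix, non-negative and finite.
#' @param cell_ids character vector of unique cell identifiers (rows).
#' @param gene_ids character vector of unique gene identifiers (columns).
#' @param labels character or factor of cell-type labels, one per cell.
#' @param view `"raw"` (counts) or `"normalized"` (log1p-CPM).
#'
#' @return An object of class `cell_matrix`: a list with elements `values`
#'   (with dimnames set), `cell_ids`, `gene_ids`, `labels` (factor) and
#'   `view`.
#' @export
cell_matrix <- function(values, cell_ids, gene_ids, labels,
                        view = c("raw", "normalized")) {
  view <- match.arg(view)
  values <- as.matrix(values)
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids))
    stop(sprintf("dimension mismatch: %d matrix rows but %d cell ids",
                 nrow(values), length(cell_ids)), call. = FALSE)
  if (ncol(values) != length(gene_ids))
    stop(sprintf("dimension mismatch: %d matrix columns but %d gene ids",
                 ncol(values), length(gene_ids)), call. = FALSE)
  if (anyDuplicated(cell_ids)) {
    dup <- cell_ids[duplicated(cell_ids)][1]
    stop(sprintf("duplicate cell id: '%s'", dup), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    stop(sprintf("duplicate gene id: '%s'", dup), call. = FALSE)
  }
  if (length(labels) != length(cell_ids))
    stop(sprintf("labels length (%d) != number of cells (%d)",
                 length(labels), length(cell_ids)), call. = FALSE)
  lab_chr <- as.character(labels)
  if (anyNA(lab_chr) || any(!nzchar(lab_chr))) {
    bad <- cell_ids[which(is.na(lab_chr) | !nzchar(lab_chr))[1]]
    stop(sprintf("empty or missing label for cell '%s'", bad), call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         labels = factor(lab_chr), view = view),
    class = "cell_matrix"
  )
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes [%s view]\n",
              nrow(x$values), ncol(x$values), x$view))
  tab <- table(x$labels)
  cat(sprintf("%d cell types: %s\n", length(tab),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Subset a cell_matrix by cells and/or genes
#'
#' @param mat a [cell_matrix()].
#' @param cells cell ids, logical mask or integer indices (default: all).
#' @param genes gene ids, logical mask or integer indices (default: all).
#' @return A `cell_matrix` restricted to the requested cells/genes, order as
#'   given.
#' @export
subset_matrix <- function(mat, cells = NULL, genes = NULL) {
  stopifnot(inherits(mat, "cell_matrix"))
  ci <- resolve_index(cells, mat$cell_ids, "cell")
  gi <- resolve_index(genes, mat$gene_ids, "gene")
  cell_matrix(mat$values[ci, gi, drop = FALSE],
              mat$cell_ids[ci], mat$gene_ids[gi],
              as.character(mat$labels)[ci], view = mat$view)
}

resolve_index <- function(idx, ids, what) {
  if (is.null(idx)) return(seq_along(ids))
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos))
      stop(sprintf("unknown %s id(s): %s", what,
                   paste(idx[is.na(pos)][seq_len(min(3, sum(is.na(pos))))],
                         collapse = ", ")), call. = FALSE)
    return(pos)
  }
  if (is.logical(idx)) return(which(idx))
  as.integer(idx)
}

#' Library-size normalization to the log1p-CPM view
#'
#' Counts-per-million scaling of each cell followed by `log1p`, the
#' conventional single-cell normalization. Cells with zero total counts are
#' left at zero.
#'
#' @param mat a raw-view [cell_matrix()].
#' @param scale_factor library-size target, default `1e6` (CPM).
#' @return A `cell_matrix` with `view = "normalized"`.
#' @export
normalize_matrix <- function(mat, scale_factor = 1e6) {
  stopifnot(inherits(mat, "cell_matrix"))
  if (mat$view == "normalized") return(mat)
  lib <- rowSums(mat$values)
  lib[lib == 0] <- 1
  vals <- log1p(mat$values / lib * scale_factor)
  cell_matrix(vals, mat$cell_ids, mat$gene_ids,
              as.character(mat$labels), view = "normalized")
}
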