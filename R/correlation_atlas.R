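utils::globalVariables(c("umap1", "umap2", "label"))

#' Gene-gene Pearson correlation screen
#'
#' Pairwise Pearson correlation over all cells for the selected genes, with
#' the pairs exceeding the high-correlation threshold (`r > threshold`,
#' strictly, signed) listed explicitly. Constant-expression genes have no
#' defined correlation and are excluded with a warning.
#'
#' @param mat a [cell_matrix()] (at least 2 cells).
#' @param genes gene ids to screen (default: all).
#' @param threshold high-correlation cutoff, default 0.8.
#' @return An object of class `correlation_report`: `matrix` (symmetric,
#'   unit diagonal), `high_pairs` (data.frame gene_a < gene_b, r),
#'   `threshold`, `excluded` (constant genes).
#' @export
gene_correlation <- function(mat, genes = NULL, threshold = 0.8) {
  stopifnot(inherits(mat, "cell_matrix"))
  if (nrow(mat$values) < 2)
    stop("need at least 2 cells for correlation", call. = FALSE)
  genes <- genes %||% mat$gene_ids
  x <- subset_matrix(mat, genes = genes)$values
  sds <- apply(x, 2, stats::sd)
  excluded <- colnames(x)[sds == 0]
  if (length(excluded)) {
    warning(sprintf("constant-expression gene(s) excluded: %s",
                    paste(utils::head(excluded, 5), collapse = ", ")),
            call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
  }
  cm <- stats::cor(x)
  ut <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  high <- data.frame(gene_a = rownames(cm)[ut[, 1]],
                     gene_b = colnames(cm)[ut[, 2]],
                     r = cm[ut])
  high <- high[order(-high$r, high$gene_a, high$gene_b), , drop = FALSE]
  rownames(high) <- NULL
  structure(list(matrix = cm, high_pairs = high, threshold = threshold,
                 excluded = excluded), class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> %d genes, %d pair(s) with r > %.2f\n",
              ncol(x$matrix), nrow(x$high_pairs), x$threshold))
  invisible(x)
}

#' Gene-to-cell-type point-biserial correlation
#'
#' For each gene and cell type, the Pearson correlation between the gene's
#' expression vector and the 0/1 type-membership indicator — the
#' point-biserial association of a gene with a type. Constant genes are
#' reported as `NA` with a warning.
#'
#' @param mat a [cell_matrix()] with at least 2 cell types.
#' @param genes gene ids (default: all).
#' @return A genes x types numeric matrix with values in `[-1, 1]`.
#' @export
gene_type_correlation <- function(mat, genes = NULL) {
  stopifnot(inherits(mat, "cell_matrix"))
  if (nlevels(droplevels(mat$labels)) < 2)
    stop("need at least 2 cell types", call. = FALSE)
  genes <- genes %||% mat$gene_ids
  x <- subset_matrix(mat, genes = genes)$values
  types <- levels(droplevels(mat$labels))
  ind <- vapply(types, function(ty) as.numeric(mat$labels == ty),
                numeric(nrow(x)))
  const <- apply(x, 2, stats::sd) == 0
  if (any(const))
    warning(sprintf("constant-expression gene(s) reported as NA: %s",
                    paste(utils::head(colnames(x)[const], 5), collapse = ", ")),
            call. = FALSE)
  out <- suppressWarnings(stats::cor(x, ind))
  out[const, ] <- NA_real_
  dimnames(out) <- list(colnames(x), types)
  out
}

#' UMAP atlas of cells in any feature space
#'
#' Embeds cells into 2-D with UMAP (neighbour count 15, minimum distance
#' 0.1 by default) for atlas plots; works identically on expression views
#' and reconstructed SHAP matrices. Deterministic under the seed
#' (single-threaded SGD).
#'
#' @param features a [cell_matrix()], `shap_matrix` or numeric matrix
#'   (rows = cells); at least 3 rows.
#' @param labels per-row labels (default: taken from the container).
#' @param seed RNG seed.
#' @param n_neighbors,min_dist UMAP parameters (neighbour count is capped
#'   at `n - 1`).
#' @return A data.frame `cell_id`, `umap1`, `umap2`, `label` of class
#'   `umap_atlas`.
#' @export
umap_atlas <- function(features, labels = NULL, seed = 42,
                       n_neighbors = 15, min_dist = 0.1) {
  if (inherits(features, "cell_matrix")) {
    labels <- labels %||% as.character(features$labels)
    features <- features$values
  } else if (inherits(features, "shap_matrix")) {
    labels <- labels %||% as.character(features$labels)
    features <- features$values
  }
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 cells to embed", call. = FALSE)
  if (is.null(labels)) labels <- rep(NA_character_, n)
  nn <- max(2L, min(n_neighbors, n - 1L))
  # spectral initialization needs n > ndim + 1; tiny inputs fall back to a
  # seeded random layout
  init <- if (n <= 4) "random" else "spectral"
  emb <- run_seeded(seed,
    uwot::umap(features, n_neighbors = nn, min_dist = min_dist,
               init = init, n_threads = 1, n_sgd_threads = 0,
               batch = FALSE))
  out <- data.frame(cell_id = rownames(features) %||% as.character(seq_len(n)),
                    umap1 = emb[, 1], umap2 = emb[, 2],
                    label = as.character(labels))
  class(out) <- c("umap_atlas", "data.frame")
  out
}

#' Plot a UMAP atlas colored by cell type
#'
#' @param atlas a [umap_atlas()] result.
#' @param point_size dot size.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_atlas <- function(atlas, point_size = 0.6) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_atlas requires the ggplot2 package", call. = FALSE)
  ggplot2::ggplot(atlas, ggplot2::aes(umap1, umap2, colour = label)) +
    ggplot2::geom_point(size = point_size, alpha = 0.8) +
    ggplot2::guides(colour = ggplot2::guide_legend(
      override.aes = list(size = 3))) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = "cell type") +
    ggplot2::theme_minimal()
}
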