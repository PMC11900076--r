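#' Reconstruct the selected-gene SHAP value matrix
#'
#' Uses the additivity (local accuracy) of Shapley values: for every
#' correctly classified test cell, the row holds the attribution of each
#' selected gene toward the cell's true class, and the discarded genes'
#' contribution is folded into a per-row remainder, so
#' `base + rowSum(selected) + remainder == predicted probability` (audited
#' to `tol`).
#'
#' @param tensor an `attribution_tensor` over the test cells.
#' @param gene_set character vector of selected genes (non-empty, subset of
#'   the tensor's genes), e.g. a partition's `union_sel`.
#' @param predictions,labels as in [filter_correct()].
#' @param tol additivity audit tolerance (default 1e-6).
#' @return An object of class `shap_matrix`: `values` (correct cells x
#'   selected genes), `labels`, `base` (per-class), `remainder` (per-row
#'   excluded-gene sum), `audit_error` (max additivity violation over rows).
#' @export
reconstruct_shap_matrix <- function(tensor, gene_set, predictions = NULL,
                                    labels = NULL, tol = 1e-6) {
  stopifnot(inherits(tensor, "attribution_tensor"))
  if (length(gene_set) == 0)
    stop("gene_set is empty: a zero-column SHAP matrix is not usable",
         call. = FALSE)
  missing_genes <- setdiff(gene_set, tensor$genes)
  if (length(missing_genes))
    stop(sprintf("gene_set contains gene(s) outside the tensor: %s",
                 paste(utils::head(missing_genes, 3), collapse = ", ")),
         call. = FALSE)
  predictions <- predictions %||%
    tensor$classes[max.col(tensor$predictions, ties.method = "first")]
  labels <- labels %||% tensor$labels
  if (is.null(labels)) stop("labels are required", call. = FALSE)
  keep <- which(predictions == labels)
  if (length(keep) == 0)
    stop("no correctly classified cells to reconstruct from", call. = FALSE)
  cls_idx <- match(labels[keep], tensor$classes)
  gi <- match(gene_set, tensor$genes)

  n <- length(keep); p <- length(gene_set)
  values <- matrix(0, n, p, dimnames = list(tensor$cell_ids[keep], gene_set))
  remainder <- numeric(n)
  audit <- numeric(n)
  for (r in seq_len(n)) {
    full <- tensor$phi[keep[r], , cls_idx[r]]
    values[r, ] <- full[gi]
    remainder[r] <- sum(full[-gi])
    audit[r] <- abs(tensor$base[cls_idx[r]] + sum(full) -
                      tensor$predictions[keep[r], cls_idx[r]])
  }
  if (max(audit) > tol)
    warning(sprintf("additivity audit failed: max violation %.3g > %.3g",
                    max(audit), tol), call. = FALSE)
  structure(list(values = values, labels = labels[keep],
                 base = tensor$base, remainder = remainder,
                 gene_set = gene_set, audit_error = max(audit)),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("<shap_matrix> %d correct cells x %d genes (audit %.2g)\n",
              nrow(x$values), ncol(x$values), x$audit_error))
  invisible(x)
}

#' Cell-type importance by positive attribution mass
#'
#' Scores each cell type by the per-cell mean of its summed positive SHAP
#' entries: `score(c) = mean over c's rows of sum_g max(phi, 0)`. The
#' per-cell mean (rather than a raw sum) makes the score invariant to a
#' type's abundance, so a rare type can outrank a dominant one. Types with
#' fewer than `min_cells` correctly classified cells are excluded as
#' low-quality information.
#'
#' @param sm a [reconstruct_shap_matrix()] result.
#' @param min_cells minimum correct cells for a type to be ranked
#'   (default 5).
#' @return A data.frame of class `importance_ranking` (`cell_type`,
#'   `n_cells`, `score`, `rank`, descending score, tie-break by type name),
#'   with excluded types in `attr(, "excluded")`.
#' @export
cell_type_importance <- function(sm, min_cells = 5) {
  stopifnot(inherits(sm, "shap_matrix"))
  if (nrow(sm$values) == 0) stop("empty SHAP matrix", call. = FALSE)
  pos <- rowSums(pmax(sm$values, 0))
  types <- sort(unique(as.character(sm$labels)))
  n_cells <- vapply(types, function(ty) sum(sm$labels == ty), integer(1))
  score <- vapply(types, function(ty) mean(pos[sm$labels == ty]), numeric(1))
  low <- n_cells < min_cells
  excluded <- data.frame(
    cell_type = types[low], n_cells = n_cells[low],
    reason = rep(sprintf("fewer than %d correctly classified cells",
                         min_cells), sum(low)))
  keep <- n_cells >= min_cells
  if (!any(keep)) stop("every type fell below min_cells", call. = FALSE)
  if (all(score[keep] == 0))
    warning("all positive-SHAP scores are 0; ranking is tie-break only",
            call. = FALSE)
  ord <- order(-score[keep], types[keep])
  out <- data.frame(cell_type = types[keep][ord],
                    n_cells = as.integer(n_cells[keep][ord]),
                    score = as.numeric(score[keep][ord]),
                    rank = seq_len(sum(keep)))
  attr(out, "excluded") <- excluded
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Per-type key genes by mean positive attribution
#'
#' For each cell type, genes are ranked by the mean of their positive SHAP
#' entries over that type's rows and the top `k` are reported, ties broken
#' by gene id.
#'
#' @param sm a [reconstruct_shap_matrix()] result.
#' @param k genes per type (default 20, truncated at the column count).
#' @return A data.frame of class `key_gene_table`: `cell_type`, `rank`,
#'   `gene`, `score` (non-increasing within type).
#' @export
key_genes_per_type <- function(sm, k = 20) {
  stopifnot(inherits(sm, "shap_matrix"), k >= 1)
  k <- min(k, ncol(sm$values))
  genes <- colnames(sm$values)
  types <- sort(unique(as.character(sm$labels)))
  out <- lapply(types, function(ty) {
    block <- sm$values[sm$labels == ty, , drop = FALSE]
    score <- colMeans(pmax(block, 0))
    ord <- order_desc_then_id(score, genes)[seq_len(k)]
    data.frame(cell_type = ty, rank = seq_len(k), gene = genes[ord],
               score = as.numeric(score[ord]))
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  class(out) <- c("key_gene_table", "data.frame")
  out
}

#' Retrain a classifier on the reconstructed SHAP matrix
#'
#' Treats the SHAP matrix rows as samples and the selected genes'
#' attributions as features, splits them 7:3 stratified by type, re-runs the
#' randomized search, and reports held-out accuracy — the check that the
#' selected genes' attributions retain (nearly all of) the class
#' information. Types with fewer than `2 * cv_folds` rows are dropped with a
#' warning.
#'
#' @param sm a [reconstruct_shap_matrix()] result.
#' @param spec a [search_spec()].
#' @param split_seed seed of the row split (default 42).
#' @param ratio train fraction (default 0.7).
#' @return A list: `model`, `accuracy` (held-out), `evaluation`,
#'   `dropped_types`.
#' @export
retrain_on_shap_matrix <- function(sm, spec = search_spec(),
                                   split_seed = 42, ratio = 0.7) {
  stopifnot(inherits(sm, "shap_matrix"))
  tab <- table(as.character(sm$labels))
  min_rows <- 2L * spec$cv_folds
  dropped <- names(tab)[tab < min_rows]
  if (length(dropped))
    warning(sprintf("type(s) with fewer than %d rows dropped: %s", min_rows,
                    paste(dropped, collapse = ", ")), call. = FALSE)
  keep <- !(as.character(sm$labels) %in% dropped)
  labs <- as.character(sm$labels)[keep]
  if (length(unique(labs)) < 2)
    stop("fewer than 2 types remain; cannot retrain on the SHAP matrix",
         call. = FALSE)
  x <- sm$values[keep, , drop = FALSE]
  # SHAP features are signed; shift into the non-negative range the
  # expression container expects (a per-column constant shift is invisible
  # to axis-aligned trees)
  shift <- pmin(0, apply(x, 2, min))
  mat <- cell_matrix(sweep(x, 2, shift), rownames(x), colnames(x), labs,
                     view = "normalized")
  split <- split_train_test(mat, ratio = ratio, seed = split_seed)
  model <- tune_and_train(split$train, spec)
  ev <- evaluate(model, split$test)
  model$abp <- ev$accuracy
  list(model = model, accuracy = ev$accuracy, evaluation = ev,
       dropped_types = dropped)
}
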