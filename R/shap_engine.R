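#' Stratified background sample for interventional attribution
#'
#' Draws up to `n` cells from a reference set (normally the training split),
#' stratified by label so every type contributes, for use as the background
#' distribution of [attribute()].
#'
#' @param mat a [cell_matrix()].
#' @param n maximum background size (default 128).
#' @param seed RNG seed.
#' @return A `cell_matrix` with at most `n` cells.
#' @export
sample_background <- function(mat, n = 128, seed = 42) {
  stopifnot(inherits(mat, "cell_matrix"))
  if (nrow(mat$values) <= n) return(mat)
  idx <- run_seeded(seed, {
    tab <- table(mat$labels)
    take <- stats::setNames(pmax(1L, as.integer(round(n * tab / sum(tab)))),
                            names(tab))
    take <- pmin(take, stats::setNames(as.integer(tab), names(tab)))
    picked <- unlist(lapply(names(tab), function(ty) {
      rows <- which(mat$labels == ty)
      sample(rows, take[[ty]])
    }))
    if (length(picked) > n) picked <- sample(picked, n)
    if (length(picked) < n) {
      pool <- setdiff(seq_along(mat$cell_ids), picked)
      picked <- c(picked, sample(pool, n - length(picked)))
    }
    sort(picked)
  })
  subset_matrix(mat, cells = idx)
}

#' Interventional Shapley attribution of forest predictions
#'
#' Computes, for every cell, gene and class, the exact Shapley value of the
#' gene in the interventional game `v(S) = E_background[f_class(x_S,
#' Z_{not S})]`: coalition members take the cell's expression, the rest are
#' drawn from the background set. Attributions satisfy local accuracy —
#' `base[class] + sum_genes(phi) == predicted probability` up to floating
#' point — and a gene used by no tree receives exactly 0.
#'
#' @param model a `cell_model`.
#' @param cells a [cell_matrix()] (typically the test split) to attribute.
#' @param background a [cell_matrix()] or matrix of background cells
#'   (typically [sample_background()] of the training split).
#' @return An object of class `attribution_tensor`: `phi` (cells x genes x
#'   classes array), `base` (named per-class expected prediction over the
#'   background), `predictions` (cells x classes probabilities),
#'   `background_ids`, `cell_ids`, `labels`.
#' @export
attribute <- function(model, cells, background) {
  stopifnot(inherits(model, "cell_model"))
  x <- model_feature_matrix(model, cells)
  bg <- model_feature_matrix(model, background)
  if (nrow(bg) == 0) stop("empty background", call. = FALSE)
  phi <- cpp_shap_interventional(model$forest, x, bg,
                                 length(model$classes))
  dimnames(phi) <- list(rownames(x), model$genes, model$classes)
  base_pred <- cpp_forest_predict(model$forest, bg)
  base <- colMeans(base_pred)
  names(base) <- model$classes
  pred <- cpp_forest_predict(model$forest, x)
  colnames(pred) <- model$classes
  rownames(pred) <- rownames(x)
  structure(list(
    phi = phi, base = base, predictions = pred,
    background_ids = rownames(bg), cell_ids = rownames(x),
    labels = if (inherits(cells, "cell_matrix"))
      as.character(cells$labels) else NULL,
    classes = model$classes, genes = model$genes),
    class = "attribution_tensor")
}

#' @export
print.attribution_tensor <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf(
    "<attribution_tensor> %d cells x %d genes x %d classes (background %d)\n",
    d[1], d[2], d[3], length(x$background_ids)))
  cat(sprintf("max |base + sum(phi) - prediction| = %.3g\n",
              local_accuracy_error(x)))
  invisible(x)
}

#' Largest local-accuracy violation of an attribution tensor
#'
#' @param tensor an `attribution_tensor`.
#' @return `max |base + sum_genes(phi) - predicted probability|` over all
#'   cells and classes.
#' @export
local_accuracy_error <- function(tensor) {
  stopifnot(inherits(tensor, "attribution_tensor"))
  recon <- apply(tensor$phi, c(1, 3), sum) +
    matrix(tensor$base, nrow = dim(tensor$phi)[1],
           ncol = dim(tensor$phi)[3], byrow = TRUE)
  max(abs(recon - tensor$predictions))
}

# Independent plain-R tree walk used only by the exhaustive oracle, so the
# oracle shares no code path with the C++ engine.
r_predict_forest <- function(model, x) {
  n <- nrow(x); K <- length(model$classes)
  out <- matrix(0, n, K)
  for (tr in model$forest) {
    for (i in seq_len(n)) {
      node <- 1L
      while (tr$left[node] >= 0L) {
        node <- if (x[i, tr$feature[node] + 1L] <= tr$threshold[node])
          tr$left[node] + 1L else tr$right[node] + 1L
      }
      out[i, ] <- out[i, ] + tr$probs[node, ]
    }
  }
  out / length(model$forest)
}

#' Exhaustive coalition-enumeration Shapley oracle
#'
#' Computes exact Shapley values for a single cell by enumerating all
#' `2^p` gene coalitions of the interventional game and combining marginal
#' contributions with factorial weights. Intentionally brute force — it
#' verifies [attribute()] — so it refuses more than `max_genes` genes.
#'
#' @param model a `cell_model`.
#' @param cell a single-row matrix/vector of expression values (gene-named)
#'   or a one-cell [cell_matrix()].
#' @param background background cells as for [attribute()].
#' @param max_genes refusal bound on the enumeration (default 12).
#' @return A genes x classes matrix of Shapley values.
#' @export
brute_force_shapley <- function(model, cell, background, max_genes = 12) {
  stopifnot(inherits(model, "cell_model"))
  p <- length(model$genes)
  if (p > max_genes)
    stop(sprintf(
      "exhaustive enumeration over 2^%d coalitions refused (bound: %d genes)",
      p, max_genes), call. = FALSE)
  if (is.null(dim(cell)) && !inherits(cell, "cell_matrix"))
    cell <- matrix(cell, nrow = 1, dimnames = list(NULL, names(cell)))
  x <- model_feature_matrix(model, cell)
  if (nrow(x) != 1) stop("oracle attributes one cell at a time", call. = FALSE)
  bg <- model_feature_matrix(model, background)
  if (nrow(bg) == 0) stop("empty background", call. = FALSE)
  K <- length(model$classes)

  n_sets <- bitwShiftL(1L, p)
  v <- matrix(0, n_sets, K)  # v[S+1, ] = E_bg f(x_S, Z_-S)
  for (s in 0:(n_sets - 1L)) {
    comp <- bg
    for (j in seq_len(p))
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L) comp[, j] <- x[1, j]
    v[s + 1L, ] <- colMeans(r_predict_forest(model, comp))
  }

  fact <- factorial(0:p)
  phi <- matrix(0, p, K, dimnames = list(model$genes, model$classes))
  sizes <- vapply(0:(n_sets - 1L), function(s)
    sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L), numeric(1))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(n_sets - 1L)) {
      if (bitwAnd(s, bit) != 0L) next
      w <- fact[sizes[s + 1L] + 1L] * fact[p - sizes[s + 1L]] / fact[p + 1L]
      phi[j, ] <- phi[j, ] + w * (v[bitwOr(s, bit) + 1L, ] - v[s + 1L, ])
    }
  }
  phi
}

#' Split attributions by class, keeping only correctly classified cells
#'
#' For each class, retains the cells whose prediction and label both equal
#' that class and extracts their attribution slice for it; the per-class
#' blocks are also concatenated into one long table with a class column.
#'
#' @param tensor an `attribution_tensor`.
#' @param predictions predicted labels aligned with the tensor's cells
#'   (default: argmax of the stored probabilities).
#' @param labels true labels (default: the labels stored in the tensor).
#' @return A list of class `class_attributions`: `blocks` (class -> cells x
#'   genes matrix of that class's phi for its correct cells), `table` (one
#'   data.frame: cell_id, cell_type, then gene columns), `n_correct`.
#' @export
filter_correct <- function(tensor, predictions = NULL, labels = NULL) {
  stopifnot(inherits(tensor, "attribution_tensor"))
  predictions <- predictions %||%
    tensor$classes[max.col(tensor$predictions, ties.method = "first")]
  labels <- labels %||% tensor$labels
  if (is.null(labels))
    stop("labels are required (tensor carries none)", call. = FALSE)
  n <- dim(tensor$phi)[1]
  if (length(predictions) != n || length(labels) != n)
    stop("predictions/labels are not aligned with the tensor cells",
         call. = FALSE)
  blocks <- list()
  rows <- list()
  for (cls in tensor$classes) {
    keep <- which(predictions == cls & labels == cls)
    block <- tensor$phi[keep, , cls, drop = FALSE]
    dim(block) <- c(length(keep), dim(tensor$phi)[2])
    dimnames(block) <- list(tensor$cell_ids[keep], tensor$genes)
    if (length(keep) == 0)
      warning(sprintf("class '%s' has no correctly classified cells", cls),
              call. = FALSE)
    blocks[[cls]] <- block
    rows[[cls]] <- data.frame(cell_id = tensor$cell_ids[keep],
                              cell_type = rep(cls, length(keep)),
                              block, check.names = FALSE)
  }
  structure(list(blocks = blocks, table = do.call(rbind, c(rows,
                   make.row.names = FALSE)),
                 n_correct = sum(predictions == labels)),
            class = "class_attributions")
}

#' Global gene importance ranking
#'
#' Ranks genes by mean absolute attribution over cells, summed over classes
#' (the usual SHAP summary-bar ordering), descending with gene-id
#' tie-breaks.
#'
#' @param tensor an `attribution_tensor`.
#' @param k how many genes to return (default 20); if larger than the gene
#'   count the full ranking is returned with a warning.
#' @return A data.frame `gene`, `importance`, `rank` of class
#'   `gene_ranking`.
#' @export
global_gene_ranking <- function(tensor, k = 20) {
  stopifnot(inherits(tensor, "attribution_tensor"))
  if (dim(tensor$phi)[1] == 0) stop("tensor has no cells", call. = FALSE)
  # mean over cells of |phi| per class, summed over classes
  imp <- rowSums(apply(abs(tensor$phi), c(2, 3), mean))
  names(imp) <- tensor$genes
  if (k > length(imp)) {
    warning(sprintf("k = %d exceeds the %d available genes; returning all",
                    k, length(imp)), call. = FALSE)
    k <- length(imp)
  }
  ord <- order_desc_then_id(imp, tensor$genes)[seq_len(k)]
  structure(data.frame(gene = tensor$genes[ord],
                       importance = as.numeric(imp[ord]),
                       rank = seq_len(k)),
            class = c("gene_ranking", "data.frame"))
}
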