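#' Per-type top-N genes by mean attribution
#'
#' Within each class's block of correctly classified cells, genes are scored
#' by their mean attribution for that class (mean, not sum, so rare types
#' are not penalized) and the top `n_top` are kept, ties broken by gene id.
#'
#' @param blocks a `class_attributions` from [filter_correct()], or a named
#'   list of cells x genes matrices.
#' @param n_top list length per type (default 500, truncated at the gene
#'   count).
#' @return A named list of class `per_type_top_genes`: type -> ordered gene
#'   character vector. Types with empty blocks are skipped with a warning.
#' @export
per_type_top_genes <- function(blocks, n_top = 500) {
  if (inherits(blocks, "class_attributions")) blocks <- blocks$blocks
  stopifnot(is.list(blocks), !is.null(names(blocks)))
  out <- list()
  for (cls in names(blocks)) {
    block <- blocks[[cls]]
    if (is.null(block) || nrow(block) == 0) {
      warning(sprintf("class '%s' has an empty attribution block; skipped",
                      cls), call. = FALSE)
      next
    }
    score <- colMeans(block)
    genes <- colnames(block)
    ord <- order_desc_then_id(score, genes)
    out[[cls]] <- genes[ord][seq_len(min(n_top, length(genes)))]
  }
  structure(out, class = "per_type_top_genes")
}

#' Partition per-type gene lists into co-expressed / specific / union sets
#'
#' Following the upset-style reading of per-type top-gene lists:
#' *co-expressed* genes appear in every list, *specifically expressed* genes
#' in exactly one, `union_sel` is their union (the "co + specific" working
#' set), and `all_distinct` is the distinct union of all lists. Genes in 2
#' to K-1 lists belong to neither co nor specific.
#'
#' @param lists a [per_type_top_genes()] result or named list of gene id
#'   vectors (at least 2).
#' @return An object of class `gene_partition`: `co_expressed`, `specific`,
#'   `union_sel`, `all_distinct` (sorted character vectors), `membership`
#'   (data.frame gene, n_lists) and `counts`.
#' @export
partition_gene_sets <- function(lists) {
  if (inherits(lists, "per_type_top_genes")) lists <- unclass(lists)
  stopifnot(is.list(lists))
  if (length(lists) < 2)
    stop("need at least 2 per-type gene lists to partition", call. = FALSE)
  k <- length(lists)
  membership <- table(unlist(lapply(lists, unique)))
  genes <- sort(names(membership))
  n_lists <- as.integer(membership[genes])
  co <- genes[n_lists == k]
  specific <- genes[n_lists == 1]
  structure(list(
    co_expressed = co, specific = specific,
    union_sel = sort(union(co, specific)), all_distinct = genes,
    membership = data.frame(gene = genes, n_lists = n_lists),
    counts = c(co_expressed = length(co), specific = length(specific),
               union_sel = length(co) + length(specific),
               all_distinct = length(genes))),
    class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf(paste0("<gene_partition> %d distinct genes: %d co-expressed ",
                     "(in all lists) + %d specific (in one) = %d selected\n"),
              x$counts[["all_distinct"]], x$counts[["co_expressed"]],
              x$counts[["specific"]], x$counts[["union_sel"]]))
  invisible(x)
}

#' Write a gene partition as plain-text lists plus a membership table
#'
#' @param partition a [partition_gene_sets()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_partition <- function(partition, dir) {
  stopifnot(inherits(partition, "gene_partition"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (set in c("co_expressed", "specific", "union_sel", "all_distinct"))
    writeLines(partition[[set]], file.path(dir, paste0(set, ".txt")))
  utils::write.csv(partition$membership,
                   file.path(dir, "membership.csv"), row.names = FALSE)
  invisible(dir)
}

#' Retrain the classifier on a gene subset
#'
#' Restricts both splits to the given genes, re-runs the randomized search
#' on the same training cells, and evaluates on the same test cells, so the
#' effect of the gene set is isolated from the cell split.
#'
#' @param train,test [cell_matrix()] splits of the parent model.
#' @param gene_set character vector of gene ids (subset of the matrix
#'   genes).
#' @param spec a [search_spec()].
#' @return A list: `model` (a `cell_model` with `abp` set) and `metrics`
#'   (its [evaluate()] result on the restricted test split).
#' @export
retrain_on_subset <- function(train, test, gene_set, spec = search_spec()) {
  stopifnot(inherits(train, "cell_matrix"), inherits(test, "cell_matrix"))
  missing_genes <- setdiff(gene_set, train$gene_ids)
  if (length(missing_genes))
    stop(sprintf("gene_set contains unknown gene(s): %s",
                 paste(utils::head(missing_genes, 3), collapse = ", ")),
         call. = FALSE)
  if (length(gene_set) == 0) stop("gene_set is empty", call. = FALSE)
  model <- tune_and_train(subset_matrix(train, genes = gene_set), spec)
  metrics <- evaluate(model, subset_matrix(test, genes = gene_set))
  model$abp <- metrics$accuracy
  list(model = model, metrics = metrics)
}
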