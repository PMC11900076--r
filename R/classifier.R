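#' Randomized-search specification for the cell-type classifier
#'
#' The hyperparameter distributions of the forest search: number of trees
#' uniform on `n_trees`, feature-subset rule from `max_features` (`"auto"`
#' is the classifier meaning of that historical keyword, an alias of
#' `"sqrt"`; `"all"` uses every feature), `max_depth`, `min_split` (minimum
#' samples to split a node), `min_leaf` (minimum samples per leaf) uniform
#' on their ranges, and `bootstrap` sampled from `{TRUE, FALSE}`.
#' `n_iterations` settings are drawn and scored by `cv_folds`-fold
#' stratified cross-validation.
#'
#' @param n_trees integer range `c(lo, hi)` for the number of trees.
#' @param max_features candidate feature-subset rules.
#' @param max_depth integer range for tree depth.
#' @param min_split integer range for the minimum node size to split.
#' @param min_leaf integer range for the minimum leaf size.
#' @param bootstrap candidate bootstrap flags.
#' @param n_iterations number of random settings to evaluate.
#' @param cv_folds number of stratified CV folds.
#' @param seed RNG seed for sampling settings, folds and tree growing.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(n_trees = c(100L, 500L),
                        max_features = c("auto", "sqrt", "log2"),
                        max_depth = c(10L, 50L),
                        min_split = c(2L, 10L),
                        min_leaf = c(1L, 4L),
                        bootstrap = c(TRUE, FALSE),
                        n_iterations = 20L, cv_folds = 5L, seed = 42L) {
  stopifnot(length(n_trees) == 2, n_trees[1] <= n_trees[2],
            length(max_depth) == 2, max_depth[1] <= max_depth[2],
            length(min_split) == 2, min_split[1] <= min_split[2],
            length(min_leaf) == 2, min_leaf[1] <= min_leaf[2],
            length(max_features) >= 1, length(bootstrap) >= 1,
            n_iterations >= 1, cv_folds >= 2)
  structure(list(n_trees = as.integer(n_trees),
                 max_features = as.character(max_features),
                 max_depth = as.integer(max_depth),
                 min_split = as.integer(min_split),
                 min_leaf = as.integer(min_leaf),
                 bootstrap = as.logical(bootstrap),
                 n_iterations = as.integer(n_iterations),
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "search_spec")
}

sample_search_settings <- function(spec) {
  draw_int <- function(rng) sample(seq(rng[1], rng[2]), 1L)
  lapply(seq_len(spec$n_iterations), function(i) {
    list(n_trees = draw_int(spec$n_trees),
         max_features = sample(spec$max_features, 1L),
         max_depth = draw_int(spec$max_depth),
         min_split = draw_int(spec$min_split),
         min_leaf = draw_int(spec$min_leaf),
         bootstrap = sample(spec$bootstrap, 1L))
  })
}

#' Stratified train/test split
#'
#' Splits cells into train and test sets with per-class proportions
#' preserved (per class, `round(ratio * n)` cells to train, at least one).
#' Disjoint, exhaustive and deterministic under the seed.
#'
#' @param mat a [cell_matrix()].
#' @param ratio train fraction in (0, 1); default 0.7.
#' @param seed RNG seed; default 42.
#' @return A list with `train` and `test` (`cell_matrix`) plus the id vectors
#'   `train_ids`, `test_ids`.
#' @export
split_train_test <- function(mat, ratio = 0.7, seed = 42) {
  stopifnot(inherits(mat, "cell_matrix"), ratio > 0, ratio < 1)
  idx <- run_seeded(seed, {
    train <- integer(0)
    for (ty in levels(mat$labels)) {
      rows <- which(mat$labels == ty)
      n_tr <- max(1L, min(length(rows), as.integer(round(ratio * length(rows)))))
      train <- c(train, sample(rows, n_tr))
    }
    sort(train)
  })
  test <- setdiff(seq_along(mat$cell_ids), idx)
  list(train = subset_matrix(mat, cells = idx),
       test = subset_matrix(mat, cells = test),
       train_ids = mat$cell_ids[idx], test_ids = mat$cell_ids[test])
}

mtry_from_rule <- function(rule, p) {
  switch(rule,
         all = p,
         auto = max(1L, floor(sqrt(p))),  # classifier alias of sqrt
         sqrt = max(1L, floor(sqrt(p))),
         log2 = max(1L, floor(log2(p))),
         stop(sprintf("unknown feature-subset rule '%s'", rule), call. = FALSE))
}

fit_ranger <- function(x, y, params, seed) {
  ranger::ranger(
    x = x, y = y, probability = TRUE,
    num.trees = params$n_trees,
    mtry = mtry_from_rule(params$max_features, ncol(x)),
    max.depth = params$max_depth,
    min.node.size = params$min_split,
    min.bucket = params$min_leaf,
    replace = params$bootstrap,
    sample.fraction = 1,
    seed = seed, num.threads = 1)
}

# Flatten a ranger probability forest into plain split/threshold/leaf arrays
# (0-based children and feature indices, -1 at leaves) consumable by the
# C++ prediction and attribution routines and the JSON dump.
extract_forest <- function(rf, classes) {
  pred_cols <- paste0("pred.", make.names(classes))
  lapply(seq_len(rf$num.trees), function(k) {
    ti <- ranger::treeInfo(rf, k)
    leaf <- ti$terminal
    probs <- matrix(0, nrow(ti), length(classes))
    probs[leaf, ] <- as.matrix(ti[leaf, pred_cols, drop = FALSE])
    list(left = as.integer(ifelse(leaf, -1L, ti$leftChild)),
         right = as.integer(ifelse(leaf, -1L, ti$rightChild)),
         feature = as.integer(ifelse(leaf, -1L, ti$splitvarID)),
         threshold = as.numeric(ifelse(leaf, 0, ti$splitval)),
         probs = probs)
  })
}

#' Train a probability forest with fixed hyperparameters
#'
#' Fits a `ranger` probability forest (trees vote with their leaf
#' class-frequency vectors, averaged over the forest — the sklearn
#' convention) and extracts the full tree structure so prediction and
#' Shapley attribution run off the package's own representation.
#'
#' @param train a [cell_matrix()] of training cells.
#' @param params list with `n_trees`, `max_features`, `max_depth`,
#'   `min_split`, `min_leaf`, `bootstrap` (see [search_spec()]).
#' @param seed RNG seed for tree growing.
#' @return An object of class `cell_model`: extracted `forest`, `classes`,
#'   `genes`, `params`, plus `bvs`/`abp` slots filled by [tune_and_train()]
#'   and [evaluate()].
#' @export
train_forest <- function(train, params, seed = 42L) {
  stopifnot(inherits(train, "cell_matrix"))
  if (nlevels(droplevels(train$labels)) < 2)
    stop("need at least 2 classes to train a classifier", call. = FALSE)
  y <- droplevels(train$labels)
  rf <- fit_ranger(train$values, y, params, seed)
  classes <- colnames(rf$predictions)
  structure(list(forest = extract_forest(rf, classes),
                 classes = classes, genes = train$gene_ids,
                 params = params, seed = as.integer(seed),
                 bvs = NA_real_, abp = NA_real_),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %d trees, %d genes, %d classes (%s)\n",
              length(x$forest), length(x$genes), length(x$classes),
              paste(x$classes, collapse = ", ")))
  if (!is.na(x$bvs)) cat(sprintf("BVS %.4f", x$bvs))
  if (!is.na(x$abp)) cat(sprintf("  ABP %.4f", x$abp))
  if (!is.na(x$bvs) || !is.na(x$abp)) cat("\n")
  invisible(x)
}

model_feature_matrix <- function(model, newdata) {
  x <- if (inherits(newdata, "cell_matrix")) newdata$values else
    as.matrix(newdata)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$genes))
      stop("newdata has no gene names and wrong column count", call. = FALSE)
    colnames(x) <- model$genes
  }
  pos <- match(model$genes, colnames(x))
  if (anyNA(pos))
    stop(sprintf("newdata is missing model gene(s): %s",
                 paste(utils::head(model$genes[is.na(pos)], 3), collapse = ", ")),
         call. = FALSE)
  x[, pos, drop = FALSE]
}

#' Predict cell types or class probabilities
#'
#' @param object a `cell_model`.
#' @param newdata a [cell_matrix()] or numeric matrix with gene columns.
#' @param type `"prob"` for the cells x classes probability matrix,
#'   `"class"` for the argmax label (ties to the first class).
#' @param ... unused.
#' @return A probability matrix or a character vector of labels.
#' @export
predict.cell_model <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  x <- model_feature_matrix(object, newdata)
  pr <- cpp_forest_predict(object$forest, x)
  colnames(pr) <- object$classes
  rownames(pr) <- rownames(x)
  if (type == "prob") return(pr)
  object$classes[max.col(pr, ties.method = "first")]
}

#' Randomized hyperparameter search with stratified cross-validation
#'
#' Draws `n_iterations` settings from the spec, scores each by mean
#' plain accuracy over `cv_folds` stratified folds of the training cells,
#' refits the best setting on the full training set, and records the best
#' mean CV accuracy as the model's BVS. Deterministic under the spec seed.
#'
#' @param train a [cell_matrix()] of training cells.
#' @param spec a [search_spec()].
#' @return A `cell_model` with `bvs` and `best` (the winning setting) set.
#' @export
tune_and_train <- function(train, spec = search_spec()) {
  stopifnot(inherits(train, "cell_matrix"), inherits(spec, "search_spec"))
  y <- droplevels(train$labels)
  if (nlevels(y) < 2)
    stop("need at least 2 classes to train a classifier", call. = FALSE)
  tab <- table(y)
  if (any(tab < spec$cv_folds))
    stop(sprintf(
      paste0("class '%s' has %d cells, fewer than cv_folds = %d; ",
             "balance the training data first"),
      names(tab)[which.min(tab)], min(tab), spec$cv_folds), call. = FALSE)
  x <- train$values

  res <- run_seeded(spec$seed, {
    settings <- sample_search_settings(spec)
    folds <- integer(length(y))
    for (ty in levels(y)) {
      rows <- sample(which(y == ty))
      folds[rows] <- rep_len(seq_len(spec$cv_folds), length(rows))
    }
    scores <- vapply(settings, function(par) {
      acc <- vapply(seq_len(spec$cv_folds), function(f) {
        tr <- folds != f
        rf <- fit_ranger(x[tr, , drop = FALSE], droplevels(y[tr]), par,
                         seed = spec$seed + f)
        pr <- stats::predict(rf, data = x[!tr, , drop = FALSE],
                             num.threads = 1)$predictions
        pred <- colnames(pr)[max.col(pr, ties.method = "first")]
        mean(pred == as.character(y[!tr]))
      }, numeric(1))
      mean(acc)
    }, numeric(1))
    list(settings = settings, scores = scores)
  })

  best_i <- which.max(res$scores)  # first maximum: deterministic tie-break
  model <- train_forest(train, res$settings[[best_i]], seed = spec$seed)
  model$bvs <- res$scores[best_i]
  model$best <- res$settings[[best_i]]
  model$search <- data.frame(
    iteration = seq_along(res$scores), cv_accuracy = res$scores,
    n_trees = vapply(res$settings, `[[`, integer(1), "n_trees"),
    max_features = vapply(res$settings, `[[`, character(1), "max_features"),
    max_depth = vapply(res$settings, `[[`, integer(1), "max_depth"),
    min_split = vapply(res$settings, `[[`, integer(1), "min_split"),
    min_leaf = vapply(res$settings, `[[`, integer(1), "min_leaf"),
    bootstrap = vapply(res$settings, `[[`, logical(1), "bootstrap"))
  model
}

#' Evaluate a model on held-out cells
#'
#' Computes overall accuracy (the ABP when the test set is the held-out
#' split) and per-class precision, recall and F1 (`2PR/(P+R)`, 0 when
#' `P + R == 0`). Zero-denominator precision/recall is reported as 0 with a
#' warning.
#'
#' @param model a `cell_model`.
#' @param test a [cell_matrix()] whose labels are a subset of the model's
#'   classes.
#' @return A list of class `model_evaluation`: `accuracy`, `per_class`
#'   data.frame, `confusion` table, `predictions`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "cell_model"), inherits(test, "cell_matrix"))
  truth <- as.character(test$labels)
  unknown <- setdiff(unique(truth), model$classes)
  if (length(unknown))
    stop(sprintf("test labels outside the model's classes: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  pred <- predict(model, test, type = "class")
  lev <- model$classes
  conf <- table(factor(truth, lev), factor(pred, lev), dnn = c("truth", "pred"))
  tp <- diag(conf)
  prec_den <- colSums(conf)
  rec_den <- rowSums(conf)
  if (any(prec_den[rec_den > 0] == 0))
    warning("class absent from predictions; precision reported as 0",
            call. = FALSE)
  precision <- ifelse(prec_den > 0, tp / prec_den, 0)
  recall <- ifelse(rec_den > 0, tp / rec_den, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    accuracy = mean(pred == truth),
    per_class = data.frame(cell_type = lev, n = as.integer(rec_den),
                           precision = as.numeric(precision),
                           recall = as.numeric(recall), f1 = as.numeric(f1)),
    confusion = conf, predictions = pred), class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> accuracy %.4f\n", x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a model to a JSON tree dump
#'
#' Writes every tree (children, split gene ids, thresholds, leaf class
#' probability vectors), the class order, gene order and hyperparameters, so
#' external tools — and [model_from_json()] — can reconstruct the exact
#' predictor.
#'
#' @param model a `cell_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  stopifnot(inherits(model, "cell_model"))
  trees <- lapply(model$forest, function(tr) {
    list(left = tr$left, right = tr$right, feature = tr$feature,
         threshold = tr$threshold, probs = tr$probs)
  })
  jsonlite::write_json(
    list(classes = model$classes, genes = model$genes, params = model$params,
         seed = model$seed, bvs = model$bvs, abp = model$abp, trees = trees),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  classes <- as.character(unlist(x$classes))
  forest <- lapply(x$trees, function(tr) {
    list(left = as.integer(unlist(tr$left)),
         right = as.integer(unlist(tr$right)),
         feature = as.integer(unlist(tr$feature)),
         threshold = as.numeric(unlist(tr$threshold)),
         probs = do.call(rbind, lapply(tr$probs, function(r)
           as.numeric(unlist(r)))))
  })
  params <- lapply(x$params, function(v) if (is.list(v)) unlist(v) else v)
  structure(list(forest = forest, classes = classes,
                 genes = as.character(unlist(x$genes)),
                 params = params, seed = x$seed,
                 bvs = as.numeric(x$bvs %||% NA_real_),
                 abp = as.numeric(x$abp %||% NA_real_)),
            class = "cell_model")
}
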