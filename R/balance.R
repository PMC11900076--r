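#' Build a resampling scheme targeting one cell type's count
#'
#' Every class is brought to the target type's cell count: classes with more
#' cells are under-sampled, classes with fewer are over-sampled
#' (SMOTE-style), and the target itself is kept. `target_type = "RAW"` keeps
#' every class untouched. One scheme per cell type plus RAW forms the
#' balance ladder.
#'
#' @param class_counts named integer vector of per-class cell counts.
#' @param target_type one of `names(class_counts)` or `"RAW"`.
#' @return An object of class `balancing_scheme`: `target_type`,
#'   `target_count` (`NA` for RAW), and `actions` (class ->
#'   `"undersample"`/`"oversample"`/`"keep"`).
#' @export
build_scheme <- function(class_counts, target_type) {
  stopifnot(length(class_counts) >= 1, !is.null(names(class_counts)))
  if (identical(target_type, "RAW")) {
    actions <- stats::setNames(rep("keep", length(class_counts)),
                               names(class_counts))
    return(structure(list(target_type = "RAW", target_count = NA_integer_,
                          actions = actions), class = "balancing_scheme"))
  }
  if (!target_type %in% names(class_counts))
    stop(sprintf("unknown target type '%s'; valid types: %s, RAW",
                 target_type, paste(names(class_counts), collapse = ", ")),
         call. = FALSE)
  target <- as.integer(class_counts[[target_type]])
  actions <- vapply(class_counts, function(n) {
    if (n > target) "undersample" else if (n < target) "oversample" else "keep"
  }, character(1))
  structure(list(target_type = target_type, target_count = target,
                 actions = actions), class = "balancing_scheme")
}

#' @export
print.balancing_scheme <- function(x, ...) {
  if (identical(x$target_type, "RAW")) {
    cat("<balancing_scheme> RAW (all classes kept)\n")
  } else {
    cat(sprintf("<balancing_scheme> target '%s' (%d cells/class): %s\n",
                x$target_type, x$target_count,
                paste(sprintf("%s=%s", names(x$actions),
                              substr(x$actions, 1, 5)), collapse = ", ")))
  }
  invisible(x)
}

# SMOTE interpolation: each synthetic cell is x + u * (x_nn - x) with
# u ~ Uniform(0, 1) and x_nn one of the k nearest same-class neighbours.
smote_oversample <- function(block, n_new, k = 5) {
  n <- nrow(block)
  if (n == 1) return(block[rep(1, n_new), , drop = FALSE])
  k_eff <- min(k, n - 1)
  d <- as.matrix(stats::dist(block))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k_eff)])
  nn <- if (is.matrix(nn)) t(nn) else matrix(nn, ncol = 1)
  base_i <- sample.int(n, n_new, replace = TRUE)
  nn_pick <- nn[cbind(base_i, sample.int(k_eff, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  block[base_i, , drop = FALSE] +
    u * (block[nn_pick, , drop = FALSE] - block[base_i, , drop = FALSE])
}

#' Apply a balancing scheme to a training matrix
#'
#' Under-sampling draws without replacement; over-sampling keeps all
#' original cells and adds SMOTE-interpolated synthetic cells (each on the
#' segment between a class member and one of its `k` nearest same-class
#' neighbours; singleton classes fall back to duplication). Deterministic
#' under the seed. RAW returns the input unchanged.
#'
#' @param train a [cell_matrix()]; every class in the scheme must be
#'   present.
#' @param scheme a [build_scheme()] result.
#' @param seed RNG seed.
#' @param k SMOTE neighbourhood size (default 5, reduced for small
#'   classes).
#' @return A `cell_matrix` in which every class has exactly
#'   `scheme$target_count` cells (synthetic cells get `_synth` ids).
#' @export
apply_scheme <- function(train, scheme, seed = 42, k = 5) {
  stopifnot(inherits(train, "cell_matrix"),
            inherits(scheme, "balancing_scheme"))
  if (identical(scheme$target_type, "RAW")) return(train)
  missing_cls <- setdiff(names(scheme$actions), levels(droplevels(train$labels)))
  if (length(missing_cls))
    stop(sprintf("class absent from training data: %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  target <- scheme$target_count
  run_seeded(seed, {
    parts <- lapply(names(scheme$actions), function(cls) {
      rows <- which(train$labels == cls)
      block <- train$values[rows, , drop = FALSE]
      act <- scheme$actions[[cls]]
      if (act == "undersample") {
        pick <- sort(sample(seq_along(rows), target))
        list(values = block[pick, , drop = FALSE],
             ids = train$cell_ids[rows][pick],
             labels = rep(cls, target))
      } else if (act == "oversample") {
        n_new <- target - length(rows)
        synth <- smote_oversample(block, n_new, k)
        list(values = rbind(block, synth),
             ids = c(train$cell_ids[rows],
                     sprintf("%s_synth%04d", cls, seq_len(n_new))),
             labels = rep(cls, target))
      } else {
        list(values = block, ids = train$cell_ids[rows],
             labels = rep(cls, length(rows)))
      }
    })
    cell_matrix(do.call(rbind, lapply(parts, `[[`, "values")),
                unlist(lapply(parts, `[[`, "ids")),
                train$gene_ids,
                unlist(lapply(parts, `[[`, "labels")),
                view = train$view)
  })
}

#' Train the balance ladder and select the working model
#'
#' Builds the RAW scheme plus one scheme per cell type, balances the
#' training split under each (the test split is never resampled), runs the
#' randomized hyperparameter search per scheme, and evaluates every model on
#' the common test split. The selected model is the balanced (non-RAW)
#' scheme with the highest best cross-validation score (BVS); RAW is
#' reported but excluded from selection.
#'
#' @param train a [cell_matrix()]: the training split, or the full matrix
#'   when `balance_first = TRUE`.
#' @param test the common test split ([cell_matrix()]); `NULL` when
#'   `balance_first = TRUE` (each scheme is then split after balancing —
#'   the leakage-prone ordering, exposed for comparison only).
#' @param spec a [search_spec()].
#' @param seed RNG seed for the resampling draws.
#' @param k SMOTE neighbourhood size.
#' @param keep_models keep every scheme's fitted model (default: only the
#'   selected one).
#' @param balance_first balance before splitting (default `FALSE`).
#' @param ratio,split_seed split parameters used when `balance_first`.
#' @return A list of class `ladder_result`: `report` (one row per scheme:
#'   scheme, target_count, total_cells, bvs, abp), `per_class` (long
#'   per-class precision/recall/F1), `selected` (scheme name),
#'   `selected_model` (a `cell_model`), `models` (if kept).
#' @export
run_ladder <- function(train, test = NULL, spec = search_spec(), seed = 42,
                       k = 5, keep_models = FALSE, balance_first = FALSE,
                       ratio = 0.7, split_seed = 42) {
  stopifnot(inherits(train, "cell_matrix"))
  if (!balance_first) stopifnot(inherits(test, "cell_matrix"))
  counts <- table(droplevels(train$labels))
  if (length(counts) < 2)
    stop("need at least 2 classes for the ladder", call. = FALSE)
  class_counts <- stats::setNames(as.integer(counts), names(counts))
  scheme_names <- c("RAW", names(class_counts))

  rows <- list(); per_class <- list(); models <- list()
  for (sn in scheme_names) {
    scheme <- build_scheme(class_counts, sn)
    balanced <- apply_scheme(train, scheme, seed = seed, k = k)
    if (balance_first) {
      sp <- split_train_test(balanced, ratio = ratio, seed = split_seed)
      balanced <- sp$train
      test_sn <- sp$test
    } else test_sn <- test
    model <- tryCatch(tune_and_train(balanced, spec), error = function(e)
      stop(sprintf("scheme '%s': %s", sn, conditionMessage(e)), call. = FALSE))
    ev <- evaluate(model, test_sn)
    model$abp <- ev$accuracy
    rows[[sn]] <- data.frame(
      scheme = sn,
      target_count = if (is.na(scheme$target_count)) NA_integer_
                     else scheme$target_count,
      total_cells = nrow(balanced$values),
      bvs = model$bvs, abp = ev$accuracy)
    pc <- ev$per_class
    pc$scheme <- sn
    per_class[[sn]] <- pc
    models[[sn]] <- model
  }
  report <- do.call(rbind, c(rows, make.row.names = FALSE))

  balanced_rows <- report[report$scheme != "RAW", ]
  sel_i <- order(-balanced_rows$bvs, balanced_rows$scheme)[1]
  selected <- balanced_rows$scheme[sel_i]
  structure(list(report = report,
                 per_class = do.call(rbind, c(per_class,
                                              make.row.names = FALSE)),
                 selected = selected,
                 selected_model = models[[selected]],
                 models = if (keep_models) models else NULL),
            class = "ladder_result")
}

#' @export
print.ladder_result <- function(x, ...) {
  cat(sprintf("<ladder_result> %d schemes, selected '%s'\n",
              nrow(x$report), x$selected))
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}
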