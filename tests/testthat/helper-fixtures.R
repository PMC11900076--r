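# Small in-code fixtures shared across the suite. Everything is generated
# fresh from seeds; nothing is read from disk.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_types = 3L, type_counts = c(50L, 50L, 10L), n_genes = 30L,
               markers_per_type = 3L, marker_fold_change = 8,
               nb_mean = 2, nb_dispersion = 1, dropout_rate = 0.2,
               gene_mean_shape = Inf, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# strongly separable: huge fold change, no dropout
separable_config <- function(seed = 1, ...)
  tiny_config(seed = seed, marker_fold_change = 50, dropout_rate = 0, ...)

fast_params <- function(n_trees = 60L)
  list(n_trees = n_trees, max_features = "sqrt", max_depth = 12L,
       min_split = 2L, min_leaf = 1L, bootstrap = TRUE)

fast_spec <- function(seed = 42L, n_iterations = 3L)
  search_spec(n_trees = c(50L, 120L), n_iterations = n_iterations,
              cv_folds = 3L, seed = seed)

# small trained model + attribution shared by several shap tests
small_attributed <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ds <- generate_dataset(separable_config(seed = 7))
    sp <- split_train_test(ds$normalized, 0.7, seed = 42)
    model <- train_forest(sp$train, fast_params(), seed = 42)
    bg <- sample_background(sp$train, 48, seed = 42)
    tens <- attribute(model, sp$test, bg)
    cache <<- list(ds = ds, sp = sp, model = model, bg = bg, tens = tens)
    cache
  }
})

# study-like fixture pipeline shared by the acceptance checks: ~960 cells,
# 200 genes, ladder-selected model, attribution of the full test split.
# Search budget kept small (the vignette documents the problem sizes).
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- study_like_config(scale = 0.14, seed = 42)
    ds <- generate_dataset(cfg)
    sp <- split_train_test(ds$normalized, 0.7, seed = 42)
    spec <- search_spec(n_trees = c(100L, 300L), n_iterations = 2L,
                        cv_folds = 3L, seed = 42L)
    lad <- suppressWarnings(
      run_ladder(sp$train, sp$test, spec = spec, seed = 42))
    bg <- sample_background(sp$train, 96, seed = 42)
    tens <- attribute(lad$selected_model, sp$test, bg)
    tops <- suppressWarnings(per_type_top_genes(filter_correct(tens), 500))
    part <- partition_gene_sets(tops)
    sm <- reconstruct_shap_matrix(tens, part$union_sel)
    cache <<- list(cfg = cfg, ds = ds, sp = sp, spec = spec, ladder = lad,
                   bg = bg, tens = tens, partition = part, sm = sm)
    cache
  }
})

# squared distance from a synthetic cell to the nearest segment between an
# ordered pair of same-class original cells (SMOTE geometry oracle)
smote_segment_residual <- function(synth, originals) {
  res <- Inf
  n <- nrow(originals); p <- ncol(originals)
  for (a in seq_len(n)) {
    base <- matrix(originals[a, ], n, p, byrow = TRUE)
    d <- originals - base
    nrm2 <- rowSums(d^2)
    u <- pmax(0, pmin(1, as.numeric(d %*% (synth - originals[a, ])) /
                        pmax(nrm2, .Machine$double.xmin)))
    proj <- base + u * d
    res <- min(res, min(rowSums((proj - matrix(synth, n, p,
                                               byrow = TRUE))^2)))
  }
  res
}
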