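constant_model <- function(genes, probs = c(0.3, 0.7),
                           classes = c("A", "B")) {
  structure(list(
    forest = list(list(left = -1L, right = -1L, feature = -1L,
                       threshold = 0, probs = matrix(probs, 1))),
    classes = classes, genes = genes, params = list(), seed = 1L,
    bvs = NA_real_, abp = NA_real_), class = "cell_model")
}

# one depth-1 tree splitting on gene `split_gene` at `cut`
stump_model <- function(genes, split_gene, cut, probs_left, probs_right,
                        classes = c("A", "B")) {
  structure(list(
    forest = list(list(
      left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
      feature = c(match(split_gene, genes) - 1L, -1L, -1L),
      threshold = c(cut, 0, 0),
      probs = rbind(c(0, 0), probs_left, probs_right))),
    classes = classes, genes = genes, params = list(), seed = 1L,
    bvs = NA_real_, abp = NA_real_), class = "cell_model")
}

test_that("a constant model attributes nothing and its base is the constant", {
  genes <- c("g1", "g2", "g3")
  m <- constant_model(genes)
  cells <- matrix(runif(12), 4, 3, dimnames = list(NULL, genes))
  bg <- matrix(runif(6), 2, 3, dimnames = list(NULL, genes))
  tens <- attribute(m, cells, bg)
  expect_true(all(tens$phi == 0))
  expect_equal(as.numeric(tens$base), c(0.3, 0.7))
})

test_that("one split has the closed-form attribution f(above) - f(below)", {
  genes <- c("g1", "g2")
  m <- stump_model(genes, "g1", cut = 1, probs_left = c(0.9, 0.1),
                   probs_right = c(0.2, 0.8))
  bg <- matrix(c(0.5, 0.3, 5, 2), 2, 2,
               dimnames = list(NULL, genes))  # g1 both below the cut
  cell <- matrix(c(3, 1), 1, 2, dimnames = list(NULL, genes))  # above
  tens <- attribute(m, cell, bg)
  expect_equal(tens$phi[1, "g1", "A"], 0.2 - 0.9)
  expect_equal(tens$phi[1, "g1", "B"], 0.8 - 0.1)
  expect_equal(tens$phi[1, "g2", "A"], 0)
  expect_equal(local_accuracy_error(tens), 0)
})

test_that("local accuracy holds for every cell and class on a real forest", {
  fx <- small_attributed()
  expect_lt(local_accuracy_error(fx$tens), 1e-6)
})

test_that("genes used by no tree receive exactly zero attribution", {
  # pad the model's gene space with phantom genes no tree can reference
  fx <- small_attributed()
  model <- fx$model
  phantom <- c("zz_unused1", "zz_unused2")
  model$genes <- c(model$genes, phantom)
  pad <- function(m) {
    v <- cbind(m$values, matrix(runif(nrow(m$values) * 2), ncol = 2))
    colnames(v) <- model$genes
    v
  }
  tens <- attribute(model, pad(fx$sp$test), pad(fx$bg))
  expect_true(all(tens$phi[, phantom, ] == 0))
  # and the used genes are attributed exactly as before
  expect_equal(tens$phi[, fx$model$genes, ], fx$tens$phi)
})

test_that("the engine matches the exhaustive coalition oracle", {
  ds <- generate_dataset(synthetic_config(
    n_types = 2, type_counts = c(60, 40), n_genes = 8, markers_per_type = 2,
    marker_fold_change = 8, dropout_rate = 0.2, gene_mean_shape = Inf,
    seed = 21))
  sp <- split_train_test(ds$normalized, 0.7, seed = 42)
  model <- train_forest(sp$train, list(
    n_trees = 5L, max_features = "sqrt", max_depth = 5L, min_split = 2L,
    min_leaf = 1L, bootstrap = TRUE), seed = 6)
  bg <- sample_background(sp$train, 64, seed = 1)
  cells <- subset_matrix(sp$test, cells = 1:6)
  tens <- attribute(model, cells, bg)
  for (i in seq_len(nrow(cells$values))) {
    oracle <- brute_force_shapley(model, subset_matrix(cells, cells = i), bg)
    expect_lt(max(abs(oracle - tens$phi[i, , ])), 1e-8)
  }
})

test_that("the oracle's single-player game is f(x) - base", {
  m <- stump_model("g1", "g1", cut = 0.5, probs_left = c(1, 0),
                   probs_right = c(0, 1))
  bg <- matrix(c(0.1, 0.2, 0.9), 3, 1, dimnames = list(NULL, "g1"))
  cell <- matrix(2, 1, 1, dimnames = list(NULL, "g1"))
  phi <- brute_force_shapley(m, cell, bg)
  f_x <- predict(m, cell)
  base <- colMeans(predict(m, bg))
  expect_equal(as.numeric(phi), as.numeric(f_x - base))
})

test_that("attributions are invariant to gene order permutations", {
  fx <- small_attributed()
  perm <- rev(seq_along(fx$model$genes))
  cells_p <- subset_matrix(fx$sp$test, genes = perm)
  bg_p <- subset_matrix(fx$bg, genes = perm)
  tens_p <- attribute(fx$model, cells_p, bg_p)
  expect_equal(tens_p$phi, fx$tens$phi)
})

test_that("the oracle refuses more genes than it can enumerate", {
  fx <- small_attributed()   # 30 genes
  expect_error(brute_force_shapley(fx$model,
                                   subset_matrix(fx$sp$test, cells = 1),
                                   fx$bg),
               "12")
})

test_that("empty background is rejected", {
  m <- constant_model(c("g1", "g2", "g3"))
  cells <- matrix(runif(6), 2, 3, dimnames = list(NULL, m$genes))
  bg <- matrix(numeric(0), 0, 3, dimnames = list(NULL, m$genes))
  expect_error(attribute(m, cells, bg), "background")
})

test_that("correct-cell filtering recounts the confusion diagonal", {
  fx <- small_attributed()
  ev <- evaluate(fx$model, fx$sp$test)
  corr <- filter_correct(fx$tens, predictions = ev$predictions,
                         labels = as.character(fx$sp$test$labels))
  expect_equal(corr$n_correct, sum(diag(ev$confusion)))
  expect_equal(sum(vapply(corr$blocks, nrow, integer(1))),
               sum(diag(ev$confusion)))
  expect_equal(nrow(corr$table), sum(diag(ev$confusion)))
  expect_true(all(corr$table$cell_type %in% fx$model$classes))
  # block contents are the matching tensor slices
  cls <- fx$model$classes[1]
  ids <- rownames(corr$blocks[[cls]])
  expect_equal(corr$blocks[[cls]],
               fx$tens$phi[ids, , cls])
})

test_that("a class with no correct cells yields an empty, flagged block", {
  fx <- small_attributed()
  n <- length(fx$tens$cell_ids)
  wrong <- rep(fx$model$classes[1], n)
  labs <- rep(fx$model$classes[2], n)
  warns <- testthat::capture_warnings(
    corr <- filter_correct(fx$tens, predictions = wrong, labels = labs))
  expect_true(any(grepl("no correctly classified", warns)))
  expect_equal(nrow(corr$blocks[[fx$model$classes[2]]]), 0)
})

test_that("global ranking recovers planted markers and handles edge cases", {
  recovered <- vapply(1:10, function(s) {
    ds <- generate_dataset(tiny_config(seed = s, n_genes = 40,
                                       markers_per_type = 4))
    sp <- split_train_test(ds$normalized, 0.7, seed = 42)
    model <- train_forest(sp$train, fast_params(40L), seed = s)
    bg <- sample_background(sp$train, 32, seed = s)
    tens <- attribute(model, sp$test, bg)
    top <- global_gene_ranking(tens, k = 12)$gene
    mean(top %in% unlist(ds$truth$marker_map))
  }, numeric(1))
  expect_gte(median(recovered), 0.8)

  fx <- small_attributed()
  zero <- fx$tens
  zero$phi[] <- 0
  rk <- global_gene_ranking(zero, k = 5)
  expect_true(all(rk$importance == 0))
  expect_identical(rk$gene, sort(fx$model$genes)[1:5])  # tie-break by id
  expect_warning(rk_all <- global_gene_ranking(fx$tens, k = 10000),
                 "exceeds")
  expect_equal(nrow(rk_all), length(fx$model$genes))
  expect_true(all(diff(rk_all$importance) <= 1e-15))
})
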