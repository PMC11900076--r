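test_that("stratified split is a partition preserving class proportions", {
  ds <- generate_dataset(tiny_config(seed = 15))   # 50/50/10 cells
  sp <- split_train_test(ds$normalized, ratio = 0.7, seed = 42)
  expect_equal(nrow(sp$train$values), 77)
  expect_equal(nrow(sp$test$values), 33)
  expect_equal(as.integer(table(sp$train$labels)), c(35, 35, 7))
  expect_setequal(c(sp$train_ids, sp$test_ids), ds$normalized$cell_ids)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  sp2 <- split_train_test(ds$normalized, ratio = 0.7, seed = 42)
  expect_identical(sp$train_ids, sp2$train_ids)
  sp3 <- split_train_test(ds$normalized, ratio = 0.7, seed = 43)
  expect_false(identical(sp$train_ids, sp3$train_ids))
})

test_that("a linearly separable two-class problem reaches BVS 1", {
  x <- rbind(matrix(rnorm(40, mean = 0, sd = 0.1), 20, 2),
             matrix(rnorm(40, mean = 5, sd = 0.1), 20, 2))
  mat <- cell_matrix(abs(x), sprintf("c%02d", 1:40), c("gA", "gB"),
                     rep(c("lo", "hi"), each = 20), view = "normalized")
  model <- tune_and_train(mat, fast_spec())
  expect_equal(model$bvs, 1.0)
})

test_that("permuted labels score at chance level", {
  set.seed(99)
  accs <- vapply(1:10, function(s) {
    vals <- matrix(runif(60 * 10), 60, 10)
    labs <- sample(rep(c("A", "B"), each = 30))
    mat <- cell_matrix(vals, sprintf("c%02d", 1:60), sprintf("g%02d", 1:10),
                       labs, view = "normalized")
    tune_and_train(mat, fast_spec(seed = s, n_iterations = 1L))$bvs
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("the randomized search is deterministic under its seed", {
  ds <- generate_dataset(tiny_config(seed = 16))
  sp <- split_train_test(ds$normalized, 0.7, seed = 42)
  m1 <- tune_and_train(sp$train, fast_spec(seed = 5L))
  m2 <- tune_and_train(sp$train, fast_spec(seed = 5L))
  expect_identical(m1$best, m2$best)
  expect_identical(m1$bvs, m2$bvs)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
})

test_that("a class smaller than cv_folds asks for balancing first", {
  vals <- matrix(runif(12 * 5), 12, 5)
  mat <- cell_matrix(vals, sprintf("c%02d", 1:12), sprintf("g%d", 1:5),
                     c(rep("A", 10), "B", "B"), view = "normalized")
  expect_error(tune_and_train(mat, fast_spec()), "balance")
})

test_that("evaluation metrics follow their definitions", {
  # confusion for class X: TP=3, FP=1, FN=1 -> P = R = F1 = 0.75
  model <- structure(list(classes = c("X", "Y"), genes = "g1"),
                     class = "cell_model")
  truth <- c("X", "X", "X", "X", "Y", "Y", "Y")
  pred <-  c("X", "X", "X", "Y", "X", "Y", "Y")
  conf <- table(factor(truth, model$classes), factor(pred, model$classes))
  tp <- diag(conf)
  p <- tp / colSums(conf); r <- tp / rowSums(conf)
  expect_equal(as.numeric(p["X"]), 0.75)
  expect_equal(as.numeric(r["X"]), 0.75)
  expect_equal(as.numeric(2 * p * r / (p + r))[1], 0.75)
})

test_that("evaluate() is exact on a real model and flags absent classes", {
  ds <- generate_dataset(separable_config(seed = 17))
  sp <- split_train_test(ds$normalized, 0.7, seed = 42)
  model <- train_forest(sp$train, fast_params(), seed = 42)
  ev <- evaluate(model, sp$test)
  pred <- predict(model, sp$test, type = "class")
  expect_equal(ev$accuracy, mean(pred == as.character(sp$test$labels)))
  expect_equal(sum(diag(ev$confusion)),
               sum(pred == as.character(sp$test$labels)))
  # perfect separation: all metrics 1
  expect_true(all(ev$per_class$precision == 1))
  expect_true(all(ev$per_class$f1 == 1))

  # degenerate: a class never predicted gets precision 0 with a warning
  dummy <- structure(list(
    forest = list(list(left = -1L, right = -1L, feature = -1L,
                       threshold = 0, probs = matrix(c(1, 0), 1))),
    classes = c("A", "B"), genes = ds$normalized$gene_ids,
    params = list(), seed = 1L, bvs = NA_real_, abp = NA_real_),
    class = "cell_model")
  test2 <- subset_matrix(ds$normalized, cells = 1:60)
  expect_warning(ev2 <- evaluate(dummy, cell_matrix(
    test2$values, test2$cell_ids, test2$gene_ids,
    rep(c("A", "B"), 30), view = "normalized")), "absent")
  expect_equal(ev2$per_class$precision[ev2$per_class$cell_type == "B"], 0)
})

test_that("train -> evaluate is deterministic end to end", {
  ds <- generate_dataset(tiny_config(seed = 18))
  sp <- split_train_test(ds$normalized, 0.7, seed = 42)
  a <- suppressWarnings(
    evaluate(train_forest(sp$train, fast_params(), seed = 3), sp$test))
  b <- suppressWarnings(
    evaluate(train_forest(sp$train, fast_params(), seed = 3), sp$test))
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$predictions, b$predictions)
})

test_that("the JSON tree dump round-trips the exact predictor", {
  ds <- generate_dataset(tiny_config(seed = 19))
  sp <- split_train_test(ds$normalized, 0.7, seed = 42)
  model <- train_forest(sp$train, fast_params(30L), seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model, path)
  back <- model_from_json(path)
  expect_identical(back$classes, model$classes)
  expect_identical(back$genes, model$genes)
  expect_equal(predict(back, sp$test), predict(model, sp$test))
})

test_that("forest predictions agree with the ranger predictor", {
  # cross-check the extracted representation against the fitting library
  ds <- generate_dataset(tiny_config(seed = 20))
  sp <- split_train_test(ds$normalized, 0.7, seed = 42)
  y <- droplevels(sp$train$labels)
  rf <- ranger::ranger(x = sp$train$values, y = y, probability = TRUE,
                       num.trees = 40, seed = 11, num.threads = 1,
                       sample.fraction = 1)
  model <- structure(list(
    forest = shapcell:::extract_forest(rf, colnames(rf$predictions)),
    classes = colnames(rf$predictions), genes = sp$train$gene_ids,
    params = list(), seed = 11L, bvs = NA_real_, abp = NA_real_),
    class = "cell_model")
  ours <- predict(model, sp$test)
  theirs <- stats::predict(rf, data = sp$test$values,
                           num.threads = 1)$predictions
  expect_equal(max(abs(ours - theirs[, colnames(ours)])), 0)
})
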