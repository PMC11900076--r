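test_that("reconstruction rows satisfy additivity with the remainder", {
  fx <- small_attributed()
  genes_all <- fx$model$genes
  sm_all <- reconstruct_shap_matrix(fx$tens, genes_all)
  expect_lt(sm_all$audit_error, 1e-6)
  # full gene set: row sum + base reproduces the predicted probability
  pred <- fx$tens$predictions
  cls <- match(as.character(sm_all$labels), fx$model$classes)
  rows <- match(rownames(sm_all$values), fx$tens$cell_ids)
  recon <- rowSums(sm_all$values) + fx$tens$base[cls]
  expect_equal(recon, pred[cbind(rows, cls)], ignore_attr = TRUE,
               tolerance = 1e-6)
  # subset: remainder carries the excluded genes
  sub <- genes_all[1:10]
  sm <- reconstruct_shap_matrix(fx$tens, sub)
  recon2 <- rowSums(sm$values) + sm$remainder + fx$tens$base[cls]
  expect_equal(recon2, pred[cbind(rows, cls)], ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("an empty gene set is rejected", {
  fx <- small_attributed()
  expect_error(reconstruct_shap_matrix(fx$tens, character(0)), "empty")
  expect_error(reconstruct_shap_matrix(fx$tens, "not_a_gene"), "outside")
})

test_that("each type's strongest column is one of its planted markers", {
  firsts <- vapply(1:10, function(s) {
    ds <- generate_dataset(tiny_config(seed = 50 + s, n_genes = 40,
                                       markers_per_type = 4,
                                       type_counts = c(60L, 40L, 30L)))
    sp <- split_train_test(ds$normalized, 0.7, seed = 42)
    model <- train_forest(sp$train, fast_params(40L), seed = s)
    bg <- sample_background(sp$train, 32, seed = s)
    tens <- attribute(model, sp$test, bg)
    sm <- reconstruct_shap_matrix(tens, ds$normalized$gene_ids)
    mean(vapply(unique(as.character(sm$labels)), function(ty) {
      block <- sm$values[sm$labels == ty, , drop = FALSE]
      top <- colnames(block)[which.max(colMeans(block))]
      top %in% ds$truth$marker_map[[ty]]
    }, logical(1)))
  }, numeric(1))
  expect_gte(median(firsts), 1)
})

test_that("importance is the per-cell mean of positive SHAP mass", {
  vals <- rbind(c(1, -2, 3),    # A: pos sum 4
                c(2, 0, 0),     # A: pos sum 2
                c(0, 1, -1))    # B: pos sum 1
  sm <- structure(list(
    values = matrix(vals, 3, 3,
                    dimnames = list(paste0("c", 1:3), paste0("g", 1:3))),
    labels = c("A", "A", "B"), base = c(A = 0.5, B = 0.5),
    remainder = numeric(3), gene_set = paste0("g", 1:3),
    audit_error = 0), class = "shap_matrix")
  imp <- cell_type_importance(sm, min_cells = 1)
  expect_equal(imp$score[imp$cell_type == "A"], 3)   # mean(4, 2)
  expect_equal(imp$score[imp$cell_type == "B"], 1)
  expect_equal(imp$cell_type[1], "A")

  # duplicating a type's rows leaves its per-cell-mean score unchanged
  sm2 <- sm
  sm2$values <- rbind(sm$values, sm$values[3, , drop = FALSE])
  rownames(sm2$values) <- paste0("c", 1:4)
  sm2$labels <- c(sm$labels, "B")
  sm2$remainder <- numeric(4)
  imp2 <- cell_type_importance(sm2, min_cells = 1)
  expect_lt(abs(imp2$score[imp2$cell_type == "B"] -
                imp$score[imp$cell_type == "B"]), 1e-12)

  # min_cells excludes small types as low-quality
  imp3 <- cell_type_importance(sm, min_cells = 2)
  expect_false("B" %in% imp3$cell_type)
  excl <- attr(imp3, "excluded")
  expect_equal(excl$cell_type, "B")

  # all non-positive entries: zero scores with a warning
  smz <- sm
  smz$values[] <- -abs(smz$values)
  expect_warning(impz <- cell_type_importance(smz, min_cells = 1), "0")
  expect_true(all(impz$score == 0))
  expect_equal(impz$cell_type, c("A", "B"))  # tie-break by name
})

test_that("key genes rank mean positive contributions per type", {
  vals <- rbind(c(5, 1, 0), c(3, 1, 0),   # A: g1 dominant
                c(0, 2, 6), c(0, 2, 4))   # B: g3 dominant
  sm <- structure(list(
    values = matrix(vals, 4, 3,
                    dimnames = list(paste0("c", 1:4), c("g1", "g2", "g3"))),
    labels = c("A", "A", "B", "B"), base = c(A = 0.5, B = 0.5),
    remainder = numeric(4), gene_set = c("g1", "g2", "g3"),
    audit_error = 0), class = "shap_matrix")
  kg <- key_genes_per_type(sm, k = 1)
  expect_equal(kg$gene[kg$cell_type == "A"], "g1")
  expect_equal(kg$gene[kg$cell_type == "B"], "g3")
  kg3 <- key_genes_per_type(sm, k = 3)
  expect_true(all(tapply(kg3$score, kg3$cell_type, function(s)
    all(diff(s) <= 1e-15))))
  # identical row blocks give identical lists
  smd <- sm
  smd$values[3:4, ] <- smd$values[1:2, ]
  kgd <- key_genes_per_type(smd, k = 3)
  expect_identical(kgd$gene[kgd$cell_type == "A"],
                   kgd$gene[kgd$cell_type == "B"])
})

test_that("key-gene recovery on the planted fixture", {
  hits <- vapply(1:10, function(s) {
    ds <- generate_dataset(tiny_config(seed = 60 + s, n_genes = 40,
                                       markers_per_type = 4))
    sp <- split_train_test(ds$normalized, 0.7, seed = 42)
    model <- train_forest(sp$train, fast_params(40L), seed = s)
    bg <- sample_background(sp$train, 32, seed = s)
    tens <- attribute(model, sp$test, bg)
    sm <- reconstruct_shap_matrix(tens, ds$normalized$gene_ids)
    kg <- key_genes_per_type(sm, k = 8)
    mean(vapply(unique(kg$cell_type), function(ty)
      mean(ds$truth$marker_map[[ty]] %in% kg$gene[kg$cell_type == ty]),
      numeric(1)))
  }, numeric(1))
  expect_gte(median(hits), 0.8)
})

test_that("retraining on the SHAP matrix separates shuffled labels at chance", {
  fx <- small_attributed()
  sm <- reconstruct_shap_matrix(fx$tens, fx$model$genes)
  rt <- suppressWarnings(
    retrain_on_shap_matrix(sm, spec = fast_spec(), split_seed = 42))
  expect_gte(rt$accuracy, 0.95)   # separable fixture: near-perfect

  accs <- vapply(1:5, function(s) {
    smx <- sm
    smx$labels <- withr::with_seed(s, sample(as.character(sm$labels)))
    suppressWarnings(
      retrain_on_shap_matrix(smx, spec = fast_spec(seed = s,
                                                   n_iterations = 1L),
                             split_seed = s)$accuracy)
  }, numeric(1))
  # chance level for ~3 balanced-ish classes, generous band
  expect_lt(mean(accs), 0.75)

  # single-type input is rejected
  one <- sm
  one$labels <- rep(as.character(sm$labels)[1], length(sm$labels))
  expect_error(suppressWarnings(retrain_on_shap_matrix(one, fast_spec())),
               "2 types")
})
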