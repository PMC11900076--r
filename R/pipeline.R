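#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the study defaults:
#' 7:3 split with seed 42, the full randomized-search settings, top-500
#' genes per type, top-20 key genes, 0.8 correlation threshold, and a
#' minimum of 5 correctly classified cells per ranked type. Balancing is
#' applied after the split by default (anti-leakage); set `balance_order =
#' "before_split"` for the alternative ordering.
#'
#' @param input_dir dataset directory for [load_matrix()], or `NULL` to
#'   simulate from `synthetic` instead.
#' @param synthetic a [synthetic_config()] used when `input_dir` is `NULL`
#'   (default: [study_like_config()] at a small scale).
#' @param ratio train fraction. @param seed master seed.
#' @param search a [search_spec()].
#' @param n_top per-type top-gene list length.
#' @param k_key key genes per type.
#' @param cor_threshold high-correlation cutoff.
#' @param min_cells low-quality exclusion threshold for the ranking.
#' @param n_background background cells for attribution.
#' @param smote_k SMOTE neighbourhood size.
#' @param balance_order `"after_split"` or `"before_split"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            synthetic = study_like_config(scale = 0.02),
                            ratio = 0.7, seed = 42,
                            search = search_spec(),
                            n_top = 500, k_key = 20, cor_threshold = 0.8,
                            min_cells = 5, n_background = 128, smote_k = 5,
                            balance_order = c("after_split",
                                              "before_split")) {
  balance_order <- match.arg(balance_order)
  stopifnot(ratio > 0, ratio < 1, inherits(search, "search_spec"))
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 ratio = ratio, seed = as.integer(seed), search = search,
                 n_top = n_top, k_key = k_key,
                 cor_threshold = cor_threshold, min_cells = min_cells,
                 n_background = n_background, smote_k = smote_k,
                 balance_order = balance_order),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()], [search_spec()] (under `search:`) or
#' [synthetic_config()] (under `synthetic:`) can be set; omitted fields
#' keep the study defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("search", "synthetic"))]
  if (!is.null(y$search)) args$search <- do.call(search_spec, y$search)
  if (!is.null(y$synthetic))
    args$synthetic <- do.call(synthetic_config, y$synthetic)
  do.call(pipeline_config, args)
}

pipeline_stage <- function(state, name, out_dir, code) {
  message(sprintf("[shapcell] stage %d/8: %s", length(state$stages) + 1, name))
  t0 <- Sys.time()
  result <- force(code)
  state$stages[[name]] <- list(
    name = name, seconds = as.numeric(Sys.time() - t0, units = "secs"))
  state[[name]] <- result
  state
}

#' Run the full pipeline
#'
#' simulate/load -> split -> balance ladder -> attribute -> select genes ->
#' reconstruct SHAP matrix -> rank cell types -> atlas, writing every
#' artifact (CSV/TSV/JSON/MTX) plus a `manifest.json` with the seeds, stage
#' timings and an md5 checksum per artifact. Re-running an identical config
#' reproduces the deterministic artifacts bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop(sprintf("input path does not exist: %s", config$input_dir),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(stages = list())

  state <- pipeline_stage(state, "data", out_dir, {
    if (is.null(config$input_dir)) {
      ds <- generate_dataset(config$synthetic)
      write_dataset(ds, file.path(out_dir, "dataset"))
      ds
    } else {
      raw <- load_matrix(config$input_dir)
      list(counts = raw, normalized = normalize_matrix(raw), truth = NULL)
    }
  })
  mat <- state$data$normalized

  state <- pipeline_stage(state, "split", out_dir, {
    split_train_test(mat, ratio = config$ratio, seed = config$seed)
  })

  state <- pipeline_stage(state, "ladder", out_dir, {
    lad <- if (config$balance_order == "before_split")
      run_ladder(mat, spec = config$search, seed = config$seed,
                 k = config$smote_k, balance_first = TRUE,
                 ratio = config$ratio, split_seed = config$seed)
    else
      run_ladder(state$split$train, state$split$test,
                 spec = config$search, seed = config$seed,
                 k = config$smote_k)
    utils::write.csv(lad$report, file.path(out_dir, "ladder_report.csv"),
                     row.names = FALSE)
    utils::write.csv(lad$per_class,
                     file.path(out_dir, "ladder_per_class.csv"),
                     row.names = FALSE)
    model_to_json(lad$selected_model, file.path(out_dir, "model.json"))
    lad
  })
  model <- state$ladder$selected_model

  state <- pipeline_stage(state, "attribute", out_dir, {
    bg <- sample_background(state$split$train, n = config$n_background,
                            seed = config$seed)
    tens <- attribute(model, state$split$test, bg)
    utils::write.csv(
      data.frame(class = tens$classes, base = as.numeric(tens$base)),
      file.path(out_dir, "base_values.csv"), row.names = FALSE)
    tens
  })

  state <- pipeline_stage(state, "select", out_dir, {
    corr <- filter_correct(state$attribute)
    tops <- per_type_top_genes(corr, n_top = config$n_top)
    part <- partition_gene_sets(tops)
    write_partition(part, file.path(out_dir, "partition"))
    list(correct = corr, tops = tops, partition = part)
  })

  state <- pipeline_stage(state, "reconstruct", out_dir, {
    sm <- reconstruct_shap_matrix(state$attribute,
                                  state$select$partition$union_sel)
    utils::write.csv(
      data.frame(cell_id = rownames(sm$values),
                 cell_type = as.character(sm$labels), sm$values,
                 check.names = FALSE),
      file.path(out_dir, "shap_matrix.csv"), row.names = FALSE)
    sm
  })

  state <- pipeline_stage(state, "rank", out_dir, {
    imp <- cell_type_importance(state$reconstruct,
                                min_cells = config$min_cells)
    keys <- key_genes_per_type(state$reconstruct, k = config$k_key)
    utils::write.csv(imp, file.path(out_dir, "importance_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(keys, file.path(out_dir, "key_genes.csv"),
                     row.names = FALSE)
    list(importance = imp, key_genes = keys)
  })

  state <- pipeline_stage(state, "atlas", out_dir, {
    atlas <- umap_atlas(state$reconstruct, seed = config$seed)
    utils::write.csv(atlas, file.path(out_dir, "atlas_shap.csv"),
                     row.names = FALSE)
    cr <- gene_correlation(mat,
                           genes = utils::head(
                             state$select$partition$union_sel, 200),
                           threshold = config$cor_threshold)
    utils::write.csv(cr$high_pairs,
                     file.path(out_dir, "high_correlation_pairs.csv"),
                     row.names = FALSE)
    list(atlas = atlas, correlation = cr)
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = config$seed, ratio = config$ratio,
    balance_order = config$balance_order,
    selected_scheme = state$ladder$selected,
    stages = lapply(state$stages, function(s) s["seconds"]),
    artifacts = stats::setNames(
      as.list(unname(tools::md5sum(files))),
      sub(paste0("^", out_dir, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(state, list(manifest = manifest)))
}
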