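#' Configuration for the synthetic single-cell generator
#'
#' Describes an imbalanced labeled single-cell dataset with planted marker
#' genes: `n_types` cell types with fixed per-type cell counts, negative
#' binomial counts with independent dropout, and `markers_per_type` disjoint
#' marker genes per type whose mean is multiplied by `marker_fold_change` in
#' their own type. Optionally one `dominant_type` is planted as the known
#' most-important type: its canonical markers get a further
#' `dominant_fold_multiplier` on the fold change, and it additionally
#' expresses a broader program of `dominant_program_genes` weakly elevated
#' genes (fold `dominant_program_fold`, below the canonical markers) — the
#' "many moderately specific genes" profile of a transcriptionally dominant
#' cell type such as a myofiber.
#'
#' Non-marker ("background") gene baseline means are drawn from a
#' Gamma(`gene_mean_shape`) distribution with mean `nb_mean`, giving the
#' long-tailed gene-mean profile of real single-cell data (a small fraction of
#' genes carries most of the expression). Marker genes keep baseline mean
#' exactly `nb_mean`, so a marker's expected count is `nb_mean *
#' marker_fold_change` in its own type and `nb_mean` elsewhere, before
#' dropout. `gene_mean_shape = Inf` fixes every baseline mean at `nb_mean`.
#'
#' @param n_types number of cell types.
#' @param type_counts integer vector of per-type cell counts
#'   (`length == n_types`, all `>= 1`).
#' @param n_genes number of genes; must admit all planted markers.
#' @param markers_per_type markers planted per type.
#' @param marker_fold_change multiplicative mean shift of a type's markers in
#'   that type (`1` = null construction).
#' @param nb_mean baseline negative-binomial mean.
#' @param nb_dispersion negative-binomial dispersion `a` in
#'   `var = mu + a * mu^2` (the DESeq2 convention; NB size = `1/a`).
#' @param dropout_rate probability in `[0, 1]` that any entry is zeroed
#'   independently after count sampling.
#' @param dominant_type optional type index (1-based) planted as most
#'   important.
#' @param dominant_program_genes size of the dominant type's auxiliary
#'   weakly-elevated gene program (disjoint from all marker sets).
#' @param dominant_program_fold fold change of the program genes in the
#'   dominant type (kept well below the canonical marker fold).
#' @param dominant_fold_multiplier extra fold multiplier for the dominant
#'   type's canonical markers.
#' @param gene_mean_shape Gamma shape of background gene baseline means.
#' @param type_names optional character names for the types.
#' @param seed integer RNG seed; same config + seed is bit-reproducible.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()], [study_like_config()]
#' @export
synthetic_config <- function(n_types, type_counts, n_genes, markers_per_type,
                             marker_fold_change = 8, nb_mean = 2,
                             nb_dispersion = 1.5, dropout_rate = 0.3,
                             dominant_type = NULL,
                             dominant_program_genes = markers_per_type,
                             dominant_program_fold = 3,
                             dominant_fold_multiplier = 2,
                             gene_mean_shape = 0.3,
                             type_names = NULL, seed = 42) {
  n_types <- as.integer(n_types)
  type_counts <- as.integer(type_counts)
  if (length(type_counts) != n_types)
    abort_config("type_counts",
                 sprintf("has length %d but n_types is %d",
                         length(type_counts), n_types))
  if (any(type_counts < 1))
    abort_config("type_counts", "must all be >= 1")
  n_markers_total <- markers_per_type * n_types +
    if (is.null(dominant_type)) 0 else dominant_program_genes
  if (n_markers_total > n_genes)
    abort_config("markers_per_type",
                 sprintf("requires %d planted genes but n_genes is %d",
                         n_markers_total, n_genes))
  if (dropout_rate < 0 || dropout_rate > 1)
    abort_config("dropout_rate", "must lie in [0, 1]")
  if (marker_fold_change <= 0) abort_config("marker_fold_change", "must be > 0")
  if (nb_mean <= 0) abort_config("nb_mean", "must be > 0")
  if (nb_dispersion <= 0) abort_config("nb_dispersion", "must be > 0")
  if (!is.null(dominant_type) &&
      (dominant_type < 1 || dominant_type > n_types))
    abort_config("dominant_type", sprintf("must be in 1..%d", n_types))
  if (is.null(type_names)) type_names <- sprintf("type%02d", seq_len(n_types))
  if (length(type_names) != n_types || anyDuplicated(type_names))
    abort_config("type_names", "must be n_types unique names")
  structure(
    list(n_types = n_types, type_counts = type_counts,
         n_genes = as.integer(n_genes),
         markers_per_type = as.integer(markers_per_type),
         marker_fold_change = marker_fold_change, nb_mean = nb_mean,
         nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
         dominant_type = dominant_type,
         dominant_program_genes = as.integer(dominant_program_genes),
         dominant_program_fold = dominant_program_fold,
         dominant_fold_multiplier = dominant_fold_multiplier,
         gene_mean_shape = gene_mean_shape,
         type_names = as.character(type_names), seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Default study-like fixture configuration
#'
#' Six cell types with counts `[4000, 1500, 800, 400, 120, 44] * scale`,
#' mirroring a skeletal-muscle-like composition: one dominant progenitor-like
#' population, a rare ~44-cell neutrophil-like class, and a
#' moderate-frequency myofiber-like type planted as the most important
#' (doubled marker fold change plus a 10-gene auxiliary program).
#'
#' @param scale multiplier on the per-type cell counts (counts are rounded,
#'   floored at 2 cells).
#' @param n_genes number of genes (default 200).
#' @param seed RNG seed.
#' @param ... further overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
study_like_config <- function(scale = 1, n_genes = 200, seed = 42, ...) {
  counts <- pmax(2L, as.integer(round(c(4000, 1500, 800, 400, 120, 44) * scale)))
  args <- list(
    n_types = 6L, type_counts = counts, n_genes = n_genes,
    markers_per_type = 10L, marker_fold_change = 8,
    nb_mean = 2, nb_dispersion = 1.5, dropout_rate = 0.3,
    dominant_type = 4L, dominant_program_genes = 10L,
    dominant_program_fold = 3, dominant_fold_multiplier = 2,
    type_names = c("FAP", "MC", "EndoC", "Myofiber", "MoMa", "Neutrophil"),
    seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

#' Generate a labeled synthetic expression matrix with planted truth
#'
#' Samples counts as NB(mean = per-gene baseline, dispersion =
#' `nb_dispersion`), multiplies each type's planted markers by
#' `marker_fold_change` in that type (times `dominant_fold_multiplier` for
#' the dominant type), then zeroes entries independently with probability
#' `dropout_rate`. Marker gene sets are disjoint across types. Identical
#' config + seed gives bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `sc_dataset` with elements:
#'   \describe{
#'     \item{counts}{raw-view [cell_matrix()] (cells x genes).}
#'     \item{normalized}{log1p-CPM view via [normalize_matrix()].}
#'     \item{truth}{`planted_truth`: `marker_map` (type -> ordered marker gene
#'       ids, disjoint across types) and `dominant_type`.}
#'   }
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run_seeded(config$seed, {
    n_genes <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(n_genes))
    n_mark <- rep(config$markers_per_type, config$n_types)
    n_prog <- if (is.null(config$dominant_type)) 0L
              else config$dominant_program_genes
    planted_idx <- sample.int(n_genes, sum(n_mark) + n_prog)
    marker_idx <- planted_idx[seq_len(sum(n_mark))]
    program_idx <- planted_idx[-seq_len(sum(n_mark))]
    marker_map <- split(gene_ids[marker_idx],
                        rep(seq_len(config$n_types), n_mark))
    names(marker_map) <- config$type_names
    marker_map <- lapply(marker_map, sort)
    program_genes <- sort(gene_ids[program_idx])

    base_mean <- rep(config$nb_mean, n_genes)
    bg <- setdiff(seq_len(n_genes), planted_idx)
    if (is.finite(config$gene_mean_shape) && length(bg)) {
      base_mean[bg] <- stats::rgamma(length(bg), shape = config$gene_mean_shape,
                                     rate = config$gene_mean_shape / config$nb_mean)
      base_mean[bg] <- pmax(base_mean[bg], 1e-8)
    }

    n_cells <- sum(config$type_counts)
    labels <- rep(config$type_names, config$type_counts)
    cell_ids <- sprintf("cell%05d", seq_len(n_cells))
    size <- 1 / config$nb_dispersion

    counts <- matrix(0L, n_cells, n_genes)
    row0 <- 0L
    for (t in seq_len(config$n_types)) {
      nt <- config$type_counts[t]
      mu <- base_mean
      fold <- config$marker_fold_change
      if (!is.null(config$dominant_type) && t == config$dominant_type) {
        fold <- fold * config$dominant_fold_multiplier
        mu[program_idx] <- mu[program_idx] * config$dominant_program_fold
      }
      mk <- match(marker_map[[t]], gene_ids)
      mu[mk] <- mu[mk] * fold
      block <- matrix(stats::rnbinom(nt * n_genes, mu = rep(mu, each = nt),
                                     size = size),
                      nrow = nt, ncol = n_genes)
      counts[row0 + seq_len(nt), ] <- block
      row0 <- row0 + nt
    }
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_cells * n_genes) < config$dropout_rate,
                     n_cells, n_genes)
      counts[drop] <- 0L
    }

    raw <- cell_matrix(counts, cell_ids, gene_ids, labels, view = "raw")
    truth <- structure(
      list(marker_map = marker_map,
           program_genes = program_genes,
           dominant_type = if (is.null(config$dominant_type)) NULL
                           else config$type_names[config$dominant_type]),
      class = "planted_truth")
    structure(list(counts = raw, normalized = normalize_matrix(raw),
                   truth = truth, config = config),
              class = "sc_dataset")
  })
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("<sc_dataset>\n")
  print(x$counts)
  cat(sprintf("planted markers: %s per type%s\n",
              paste(lengths(x$truth$marker_map), collapse = "/"),
              if (is.null(x$truth$dominant_type)) "" else
                sprintf("; dominant type '%s'", x$truth$dominant_type)))
  invisible(x)
}
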