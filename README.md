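# shapcell

Ranking cell-type importance and extracting key genes from labeled
single-cell expression data with tree-ensemble Shapley attribution.

## The problem

Annotated single-cell RNA-seq atlases tell you *which* cell types a tissue
contains, but not which types carry the most class-defining transcriptional
information, nor which genes make each type what it is. `shapcell`
operationalizes both questions through an interpretable classifier:

1. **Balance ladder.** A cells × genes matrix with one label per cell is
   split 7:3 (stratified, seed 42). Because compositions are extremely
   skewed (a dominant progenitor population next to a ~44-cell rare type),
   the training split is re-balanced under a *ladder* of resampling
   schemes — the raw data plus one scheme per cell type, each equalizing
   every class to that type's count by under-sampling (without replacement)
   and SMOTE over-sampling (synthetic cells `x + u·(x_nn − x)`,
   `u ~ U(0,1)`, `x_nn` a same-class nearest neighbour). A random forest is
   tuned per scheme by randomized hyperparameter search
   (`n_trees ∈ [100,500]`, feature rule ∈ {auto, sqrt, log2},
   `depth ∈ [10,50]`, `min_split ∈ [2,10]`, `min_leaf ∈ [1,4]`,
   bootstrap ∈ {T,F}; 20 draws, 5-fold stratified CV), and the balanced
   scheme with the best cross-validation score (BVS) becomes the working
   model; its test accuracy is the ABP.
2. **Shapley attribution.** Per-class predictions of the working model are
   attributed to genes with *exact interventional Shapley values*
   `phi[cell, gene, class]` against a stratified training background:
   `base[class] + Σ_genes phi = predicted probability` holds to machine
   precision (local accuracy). An exhaustive coalition-enumeration oracle
   (≤ 12 genes) verifies the engine.
3. **Gene selection.** Within each class's correctly classified test cells,
   genes are ranked by mean attribution; the per-type top-500 lists are
   partitioned into *co-expressed* (in every list), *specifically
   expressed* (in exactly one) and their union — the working gene set.
4. **SHAP-matrix reconstruction.** Using additivity, the attribution of the
   selected genes toward each correct cell's true class forms a SHAP value
   matrix. A forest retrained on those rows recovers held-out accuracy
   near 1 — the selected genes' attributions retain essentially all class
   information.
5. **Importance and key genes.** Cell types are ranked by the per-cell mean
   of summed positive SHAP entries (types with < 5 correct cells are
   excluded as low-quality); each type's top-20 genes by mean positive
   attribution are its key genes. Gene–gene Pearson screens (high pairs at
   `r > 0.8`), gene–type point-biserial correlations, and UMAP atlases on
   expression or SHAP features complete the picture.

A seeded synthetic generator (negative-binomial counts, gamma-distributed
gene means, dropout, planted disjoint markers, one planted dominant type)
makes the whole pipeline testable without any download.

## Worked example

```r
library(shapcell)

cfg   <- study_like_config(scale = 0.14, seed = 42)  # 961 cells, 200 genes
ds    <- generate_dataset(cfg)
sp    <- split_train_test(ds$normalized, ratio = 0.7, seed = 42)
spec  <- search_spec(n_trees = c(100, 300), n_iterations = 2, cv_folds = 3)
lad   <- run_ladder(sp$train, sp$test, spec = spec, seed = 42)
lad$report
#>       scheme target_count total_cells    bvs    abp
#> 1        RAW           NA         672 0.9286 0.9308
#> 2      EndoC           78         468 0.9658 0.9377
#> 3        FAP          392        2352 0.9932 0.9412
#> 4         MC          147         882 0.9785 0.9308
#> 5       MoMa           12          72 0.7778 0.8547
#> 6   Myofiber           39         234 0.9274 0.9239
#> 7 Neutrophil            4          24 0.3611 0.5156
lad$selected
#> [1] "FAP"

bg    <- sample_background(sp$train, 96, seed = 42)
tens  <- attribute(lad$selected_model, sp$test, bg)
local_accuracy_error(tens)
#> [1] 1.354472e-14            # base + sum(phi) == prediction

part  <- partition_gene_sets(per_type_top_genes(filter_correct(tens), 500))
sm    <- reconstruct_shap_matrix(tens, part$union_sel)
cell_type_importance(sm)
#>   cell_type n_cells     score rank
#> 1  Myofiber      15 0.5579186    1     <- the planted dominant type
#> 2     EndoC      30 0.4976926    2
#> 3        MC      61 0.4496092    3
#> 4       FAP     166 0.3620760    4

head(key_genes_per_type(sm, k = 5)[key_genes_per_type(sm, 5)$cell_type ==
                                     "Myofiber", ])
#>  cell_type rank  gene      score
#>   Myofiber    1 g0058 0.11971039     # g0058, g0042, g0043, g0143 are
#>   Myofiber    2 g0042 0.04952542     # planted Myofiber markers
#>   Myofiber    3 g0143 0.03741922
#>   Myofiber    4 g0043 0.02776473
#>   Myofiber    5 g0065 0.02507622

retrain_on_shap_matrix(sm, spec)$accuracy
#> [1] 1
```

Reading the ladder: the raw model scores BVS 0.929 while the selected
balanced scheme (every class resampled to the dominant type's count)
reaches 0.993 — balanced rungs stay close to, here above, the raw model.
Schemes equalizing to a tiny class throw away almost all data and score
accordingly; they are reported but never win selection. The importance
ranking puts the planted dominant type first although three types are more
abundant, and its top key genes are its planted markers. The MoMa and
Neutrophil types fall below the 5-correct-cell threshold at this scale and
are excluded from the ranking as low-quality. Retraining on the
reconstructed SHAP matrix reproduces the labels perfectly: the selected
genes' attributions retain essentially all class information.

The orchestrated form of the same steps is `run_pipeline(pipeline_config(...),
out_dir)`, which writes every artifact (ladder report CSV, model JSON, gene
partition, SHAP matrix, importance ranking, key genes, UMAP atlas) plus a
`manifest.json` of seeds and checksums; YAML configuration via
`read_pipeline_config()`.

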