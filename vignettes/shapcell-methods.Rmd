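---
title: "shapcell: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{shapcell: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the bundled synthetic data can and
cannot show. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The statistical pipeline

`shapcell` treats cell-type annotation as a supervised multiclass problem —
genes are features, the annotated type is the target — and then inverts the
trained classifier into biology: which genes drive each class, and how much
class-defining information each cell type carries.

**Split.** Cells are split 7:3 into train/test, stratified per type,
default seed 42. Stratification matters because the compositions this
pipeline targets are extremely skewed (the default fixture spans a 1000:11
ratio between the largest and smallest type).

**Balance ladder.** Class imbalance is handled by resampling the *training
split only*: for a chosen reference type, every class is brought exactly to
that type's count — under-sampling without replacement above it, SMOTE
interpolation below it (a synthetic cell is `x + u(x_nn − x)` with
`u ~ U(0,1)` and `x_nn` one of the `k = 5` nearest same-class neighbours;
`k` shrinks to `n − 1` for classes of ≤ 5 cells and degenerates to
duplication for singletons). The ladder consists of the raw data plus one
such scheme per type. Each rung is tuned by randomized search (below) and
the rung with the best cross-validation score among the *balanced* schemes
becomes the working model. The raw model is reported alongside but excluded
from selection: the point of the ladder is an imbalance-robust model, and
balanced rungs trade a little overall accuracy for better rare-class recall
— on the bundled fixture the selected rung's BVS is in fact slightly above
RAW's. Balancing after the split is deliberate (synthetic cells
interpolated across a pre-split dataset leak training information into the
test set); the leakage-prone pre-split ordering is available as
`balance_order = "before_split"` / `run_ladder(balance_first = TRUE)` for
comparison, because descriptions of this design in the wild are often
ambiguous about the order.

**Classifier and search.** Probability forests (`ranger`; trees vote with
leaf class-frequency vectors, averaged — the scikit-learn convention).
Randomized search draws `n_iterations = 20` settings from: `n_trees`
uniform on [100, 500]; feature rule from {auto, sqrt, log2}; `max_depth`
[10, 50]; `min_split` [2, 10]; `min_leaf` [1, 4]; bootstrap {T, F}; each
scored by 5-fold stratified CV accuracy, best refit on the full training
split. Two notes. *(i)* "auto" is implemented as the classifier meaning of
that historical keyword — an alias of `sqrt` — not "all features", which
was only ever the regression meaning; an explicit `"all"` rule remains
available. Besides being correct, `sqrt`-type rules are also an order of
magnitude cheaper per fit. *(ii)* CV is stratified because rare classes
would otherwise vanish from folds entirely; plain (not balanced) accuracy
is the CV score.

**Interventional Shapley attribution.** For a cell `x`, background
distribution `Z` (up to 128 stratified training cells) and class `c`, the
game is `v(S) = E_Z[f_c(x_S, Z_{S̄})]`; `phi[x, g, c]` is gene `g`'s exact
Shapley value. The engine exploits the tree structure: for one `(x, z,
tree)` triple, a leaf is reached under coalition `S` iff the path features
that only `x` satisfies are all in `S` (say `p` of them) and those only `z`
satisfies are all outside (`q`), giving the closed-form per-leaf
attribution `(p−1)! q!/(p+q)!` for "in" features and `−p! (q−1)!/(p+q)!`
for "out" features. One depth-first pass per triple therefore yields exact
values — no sampling — and efficiency telescopes into the local-accuracy
identity `base_c + Σ_g phi = f_c(x)`, which the test suite asserts below
1e−6 (observed ~1e−14). The interventional (background-conditioned) game
was chosen over path-dependent conditioning because it admits an exhaustive
coalition-enumeration oracle: on ≤ 12-gene models the suite enumerates all
`2^p` coalitions with factorial weights through an independent plain-R
predictor and requires agreement within 1e−8. Unused genes receive exactly
zero (dummy), and attributions are invariant to gene order (symmetry).

**Gene selection.** Only correctly classified test cells enter
interpretation. Within class `c`'s block, gene score = mean `phi` for `c`
(mean, not sum, so rare types are not penalized); the per-type top-500
lists are partitioned into *co-expressed* genes (in all lists),
*specifically expressed* genes (in exactly one) and their union, the
working set. These definitions are the only reading under which
"co + specific = union < distinct-union" is internally consistent; genes in
2..(K−1) lists belong to neither set. Ties everywhere break by gene id.

**SHAP matrix, importance, key genes.** By additivity, restricting each
correct cell's true-class attribution vector to the working genes gives a
SHAP value matrix whose rows still carry (nearly) the full class signal — a
forest retrained on the rows (same search spec, 7:3 split of rows) scores
≥ 0.99 held-out on the bundled fixture. Cell-type importance is the
per-cell mean of summed positive entries. The per-cell *mean* (not the raw
sum) is required for the statistic to mean anything under imbalance: a
44-cell type could never out-rank a 4000-cell type on raw sums regardless
of information content. "Low-quality information" is operationalized as
types with fewer than `min_cells = 5` correctly classified test cells
(excluded with a recorded reason) — a type represented by a handful of rows
has neither a stable score nor a meaningful key-gene list. Key genes are
per-type top-20 by mean positive entry.

**Correlation screens and atlases.** Gene–gene Pearson correlation on the
expression view, with "high correlation" defined as `r > 0.8`, strictly and
signed (config-exposed); constant genes are excluded with a warning rather
than emitting NaNs. Gene–type association is the point-biserial correlation
against the 0/1 membership indicator. Atlases are UMAP embeddings
(neighbours 15, min_dist 0.1, seeded, single-threaded SGD for bit
reproducibility) of either expression or SHAP features.

## The synthetic generator

The generator emulates the statistical structure the pipeline assumes, with
known ground truth:

* **Counts.** Negative binomial with dispersion `a` (`var = mu + a mu²`,
  default `a = 1.5`), followed by independent Bernoulli dropout (default
  0.3) — the standard count-plus-zero-inflation caricature of droplet
  scRNA-seq.
* **Gene means.** Background genes draw baseline means from
  Gamma(shape 0.3, mean `nb_mean = 2`). The long gamma tail reproduces a
  robust property of real per-type expression profiles: the top decile of
  genes carries about half of all expression, which
  `decile_expression_summary()` verifies on the counts view (shares of
  total expression are a linear-scale quantity; the log1p-CPM view is the
  default for model *training*, where relative magnitudes, not shares,
  matter — which view the original analysis used is not stated anywhere,
  so both are exposed and the choice is config-level).
* **Markers.** Each type gets `markers_per_type = 10` disjoint marker genes
  whose baseline mean is pinned at `nb_mean` exactly (not gamma-drawn), so
  a marker's expected count is exactly `nb_mean × fold` (default fold 8) in
  its own type and `nb_mean` elsewhere.
* **Dominant type.** One type is planted as most important: its canonical
  markers get double fold (16) and it additionally expresses a 10-gene
  auxiliary program at fold 3 — the "broad, moderately specific program"
  profile of a transcriptionally dominant cell type. The auxiliary genes
  are recorded separately from the marker map: they supply the extra
  positive attribution mass that makes the type rank first, while staying
  below the canonical markers in every key-gene list, so marker-recovery
  checks stay well-posed. An earlier design that simply doubled the number
  of canonical markers made the top-20 recovery target arithmetically
  unreachable and was dropped.
* **Composition.** The default fixture has 6 types at counts
  [4000, 1500, 800, 400, 120, 44] × `scale` — a dominant progenitor-like
  population, a rare ~44-cell neutrophil-like class, and the planted
  dominant "Myofiber" at moderate frequency.

What the generator does *not* emulate: batch effects, doublets, ambient
RNA, trajectories/continuous states, gene–gene co-expression modules beyond
the planted program, or UMI-level noise. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
signal under realistic sparsity and imbalance — not performance on real
tissue.

## Problem sizes and numerical choices

* Test-suite fixtures run at `scale = 0.14` (961 cells) — small enough that
  the ten-seed recovery study completes in about two minutes — with
  reduced search budgets (2–3 draws, 3-fold CV) where a tuned model is
  needed; fixed mid-range forest settings (150 trees, sqrt rule, depth 20)
  where only the attribution path is under test. `scripts/acceptance.R`
  runs at `scale = 0.25` (1716 cells) with the full search grid and a
  budget of 8 draws × 3-fold CV per ladder rung. Package *defaults* keep
  the full 20 × 5 settings.
* Importance scores are compared with a strict tolerance of 1e−12 under
  row duplication (the per-cell mean makes the score exactly invariant up
  to float association order).
* Additivity audits use 1e−6; the engine's observed error is ~1e−14
  (lgamma-based coalition weights).
* Deciles: genes ranked descending with gene-id tie-breaks; when the gene
  count is not divisible by 10, the earliest (highest-expression) bins take
  the remainder — the size-weighted bin means then reconstruct the overall
  mean to 1e−9, which is asserted on every input.
* Stratified splitting rounds per class (`round(ratio · n)`, at least one
  cell in train); degenerate classes (a single cell) go to train.
* Undefined precision/recall (empty denominator) is reported as 0 with a
  warning, never NaN, so downstream aggregation stays total.

## Known limitations

* The exhaustive oracle is exponential by construction (hard cap 12 genes);
  it exists to verify the engine, not to attribute real data.
* Attribution cost scales as cells × background × total tree size; very
  deep `"all"`-rule forests on tens of thousands of cells call for
  subsampled backgrounds (the default caps at 128).
* SMOTE interpolates in the full gene space; in very high-dimensional raw
  data, nearest neighbours become less meaningful — selecting genes first
  or working on the normalized view mitigates this.
* The importance statistic deliberately normalizes away abundance; it
  answers "how much class-defining signal does a cell of this type carry",
  not "how much does this type contribute to tissue function".
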