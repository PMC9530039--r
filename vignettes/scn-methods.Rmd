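---
title: "Sliding-window structural covariance networks: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sliding-window structural covariance networks: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The scientific problem

A structural covariance network (SCN) treats the brain's cortical parcels as
nodes and the across-subject correlation of a morphometric measure — here
cortical thickness on the 68-parcel Desikan–Killiany (DK) atlas — as edges.
Because one correlation matrix needs many subjects, SCNs are group-level
constructs: a single cohort yields a single network, and the interesting
questions (does network topology differ between clinical groups? does it
change with age?) require a way to generate *families* of networks per group
and a statistic defined on them.

`scnet` implements the sliding age-window design: subjects of one group are
sorted by age and a window of `width` subjects slides in steps of `step`
subjects, yielding `floor((n - width) / step) + 1` overlapping windows. Each
window contributes one 68×68 Pearson correlation matrix, so each group
contributes a sequence of age-localized networks. The window itself is the
age control (all subjects in a window have similar ages); an optional
`residualize_age` flag additionally removes the within-window linear age
trend as a sensitivity analysis.

## From correlations to graphs

Each correlation matrix is binarized over a sparsity grid (default 0.05–0.50
in steps of 0.05, where sparsity is the fraction of retained edges out of
`n(n-1)/2 = 2278`). At sparsity `s` the `round(s · 2278)` pairs with the
largest *signed* correlation are retained (positive covariance is the
structural-covariance notion of connectivity; `edge_rank = "abs"` is
available). Rounding is half-up and rank ties break lexicographically, so
edge sets are deterministic and nested across the grid.
`min_connected_sparsity()` reports the smallest sparsity (on the one-edge
grid) at which a matrix yields a single connected component, a useful
diagnostic for choosing the analyzed range.

```{r grid}
cohort <- generate_cohort(cohort_spec(seed = 1))
hc <- cohort[cohort$group == "HC", ]
r <- correlation_matrix(make_windows(hc)[[1]], hc)
min_connected_sparsity(r)
```

## Graph metrics and their exact conventions

For every window × threshold graph the package computes, in one compiled
pass:

- **Degree, triangles, clustering** `C_i = 2 t_i / (k_i (k_i - 1))`, with
  `C_i = 0` for `k_i < 2`; `C` is the node mean.
- **Nodal path length** `Nlp_i`: mean breadth-first distance to all other
  nodes. On disconnected graphs the mean runs over *reachable* nodes and the
  result is flagged; an isolated node is `NaN`. The characteristic path
  length `L` averages `Nlp` over nodes with at least one reachable partner.
- **Betweenness centrality** `Bc_i`: Brandes' algorithm summed over *ordered*
  pairs `(h, j)` and normalized by `(n-1)(n-2)`, so a star center scores
  exactly 1 and the values live in `[0, 1]`. Halve them for the
  unordered-pair convention used by e.g. `igraph::betweenness`.
- **Global / local efficiency**: mean inverse distances with the `1/∞ = 0`
  convention; `Eloc_i` is computed on the subgraph induced by the node's
  neighbors and normalized by `k_i (k_i - 1)`.
- **Modularity** `Q` and module count: Newman's quality function, evaluated
  via the community mixing matrix in which a between-module link contributes
  half to each of the two off-diagonal cells (two disjoint triangles score
  exactly `Q = 0.5`). The optimizer is a Louvain-type greedy local-move +
  aggregation scheme with a flat refinement pass and seeded random restarts.
  Like every practical modularity optimizer it is a heuristic: the test
  suite verifies the reported `Q` exactly matches Newman's formula on the
  returned partition, never exceeds the exhaustive-search optimum, and
  attains that optimum on the overwhelming majority of small random graphs
  and on planted-partition benchmarks.
- **Small-world indices**: `gamma = C / C_rand`, `lambda = L / L_rand`,
  `sigma = gamma / lambda`, where the null values are means over `n_null`
  (default 100) Maslov–Sneppen degree-preserving surrogates (10·|E|
  attempted double-edge swaps each). A random graph therefore scores
  `sigma ≈ 1` and small-world organization means `gamma > 1`, `lambda ≈ 1`,
  `sigma > 1`.

```{r toys}
# closed-form checks of the conventions
p3 <- binary_graph(3, rbind(c(1, 2), c(2, 3)))
betweenness_centrality(p3)                      # ordered-pair center = 1
two_k3 <- binary_graph(6, rbind(c(1, 2), c(1, 3), c(2, 3),
                                c(4, 5), c(4, 6), c(5, 6)))
modularity_partition(two_k3, seed = 1)$Q        # 0.5
```

## AUC summaries and group inference

Each metric's curve over the sparsity grid is reduced to its trapezoidal
area under the curve (AUC), a threshold-free scalar; a curve containing a
flagged (non-finite) value yields `NA` rather than a silently biased area.
Each window then contributes one AUC observation per metric cell (a global
metric, or one node of a nodal metric), and groups are compared with a
one-way ANOVA F plus pooled-t post-hoc contrasts on those window-level
values.

Overlapping windows are strongly dependent, so the F and t values are
descriptive only; inference comes from **subject-level permutation**: group
labels are shuffled `n_perm` times preserving group sizes, the *entire*
window → SCN → metric → AUC pipeline is re-run per relabeling (with the
identical metric-stage seed, so the statistic is a fixed function of the
labeled data), and two-sided p-values use the add-one rule
`p = (1 + #{|t*| ≥ |t|}) / (n_perm + 1)`. Benjamini–Hochberg FDR correction
is applied within families: the 68 nodes of each nodal metric per statistic,
and the global metrics together per statistic.

```{r inference}
cfg <- scn_config(width = 10, step = 3, grid = c(0.2, 0.35),
                  global_metrics = c("C", "Eglob"), nodal_metrics = "Bc",
                  n_perm = 99, seed = 1)
spec <- cohort_spec(group_names = c("patients", "controls"),
                    group_sizes = c(16, 16),
                    within_module_load = c(0.45, 0.7), seed = 5)
cmp <- compare_groups(generate_cohort(spec), cfg)
subset(as.data.frame(cmp), node == "global")
```

## The synthetic cohort generator

`generate_cohort()` draws thickness from a factor model: region `r` of a
subject in group `g` is

```
x_r = mu_r + beta (age - mean age) + s (w_g F_m(r) + c_g G + sigma eps_r)
```

with independent standard-normal community factors `F_1..F_6` (the six
lobe-like DK communities), a global factor `G` and residual noise. The
dimensionless loads determine the entire correlation structure — two
same-community regions correlate at `(w² + c²) / (w² + c² + sigma²)`, two
cross-community regions at `c² / (w² + c² + sigma²)` — while the mm-scale
`morpho_scale` (default 0.15 mm around a 2.5 mm baseline, with a mild
−0.01 mm/year age slope) keeps simulated thickness strictly positive and on
a realistic anatomical scale without touching the correlations. Defaults
emulate a three-group adult cohort (34/31/35 subjects, ages 25–50). The
generator is the package's ground-truth instrument: planted differences in
`within_module_load` must be recovered by the pipeline, and equal loads must
yield null results at the nominal FDR level (both are exercised in the test
suite).

Realism limits worth keeping in mind: real cortical thickness has
region-specific means/variances, distance- and homotopy-dependent
covariance, and non-Gaussian tails; the factor model captures none of these
beyond its block structure. It is designed for *calibration* of the
pipeline, not for simulating biology.

## Numerical and reproducibility choices

- All heavy computation (ranking, thresholding, BFS/Brandes, clustering,
  efficiencies, Louvain, rewiring) runs in one C++ translation unit with its
  own xorshift64* RNG; every window × threshold × surrogate stream is seeded
  deterministically from one master seed via named substreams
  (`derive_seed(seed, tag)`), so results are bit-reproducible across runs
  and platforms, independent of R's global RNG state.
- Edge counts use explicit half-up rounding (never banker's rounding), rank
  ties break lexicographically, and the permutation loop re-uses one
  statistic sub-seed, making `run_pipeline()` outputs byte-for-byte
  identical under a fixed seed (the run report intentionally carries no
  timestamps).
- Typical problem sizes: one full 3-group default analysis (73 windows × 10
  thresholds, nodal + global metrics, 100 surrogates) takes on the order of
  half a minute; permutation inference multiplies that by `n_perm`, so the
  5000-permutation default is an overnight-scale run while `n_perm` of a few
  hundred finishes in minutes. The compiled batch path computes roughly a
  millisecond per thresholded 68-node graph.

## Assumptions and limitations

- Pearson correlation on ~10-subject windows is noisy; window-level metric
  AUCs inherit that noise, and the permutation test (not the nominal F/t
  distributions) is the only calibrated inference.
- The sliding-window design confounds age with window index by construction;
  between-group comparisons assume comparable age distributions across
  groups.
- Sparsity thresholds below the connectivity bound produce disconnected
  graphs; distance-based metrics are then flagged and their AUCs are `NA`.
  Choose the grid (e.g. starting at `min_connected_sparsity()`) accordingly.
- Binary undirected graphs only; weighted or signed variants are out of
  scope.
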