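---
title: "drgmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{drgmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

drgmap re-implements, as tested and reusable components, a single-nucleus
RNA-seq analysis workflow for dorsal root ganglion (DRG) neurons: quality
control, graph clustering with marker-based cluster curation, cross-species
co-embedding, nearest-neighbor Kullback–Leibler (KL) divergence between
cluster distributions, and neighborhood-composition statistics for spatially
mapped cell types. This vignette documents the models, the parameters that
matter, the numerical choices, and the limits of what the bundled synthetic
data can and cannot demonstrate.

## The synthetic-data generator

Every stage is testable without external data because the generator
(`simulate_counts()`, `simulate_two_species()`, `simulate_spatial_map()`)
produces data with the statistical structure the downstream analyses assume.

**Counts.** UMI counts are drawn gene-wise from a negative binomial
parameterized by mean and shape, `var = mu + mu^2 / theta` — the standard
noise model for droplet snRNA-seq data and the model assumed by regularized
NB normalization methods. Each of `n_clusters` clusters elevates a disjoint
block of `marker_genes_per_cluster` genes by `marker_fold`; per-cell library
factors are log-normal with unit mean (`libsize_sigma`, default 0.3, the
spread typical of droplet libraries); mitochondrial genes (named with the
conventional `MT-` prefix so the default QC mask finds them) have their means
scaled so the expected mitochondrial UMI fraction equals `mito_mean_frac`.
Doublets are formed by *summing* two freshly drawn singlet profiles —
mimicking physical co-encapsulation of two nuclei — with the two parents
drawn from distinct clusters with probability 0.75, the heterotypic bias that
nearest-neighbor doublet detectors assume. The doublet rate default (0.05) is
a field convention, not a measured value. Identical config plus seed gives
bit-identical output.

**Two species.** `simulate_two_species()` writes species A gene names in
ALL-CAPS and species B in title case over a shared stem universe, so
orthology is exactly the case-insensitive match that `harmonize_genes()`
performs. Paired clusters share their marker stems except for a
`divergence_frac` fraction swapped for species-specific markers; 5% of each
species' genes are private so the gene intersection is proper. This encodes
cross-species divergence purely in expression programs, with no orthology
table needed.

**Spatial maps.** `csr` mode places points uniformly with labels i.i.d. from
`label_props` — the null of the neighborhood analysis, where labels are
independent of position. `thomas` mode scatters each label's points around
label-specific parents (Gaussian sd `parent_sigma`), producing the
aggregation of like cell types that the alternative hypothesis describes.
Defaults (800 points, two labels at 50:50, 10 parents, sd 50 µm on a
1.5 mm field) mirror the scale of the ISH analysis this emulates (~800
annotated single-positive neurons).

**What the generator does not emulate:** ambient RNA, batch or donor
structure, read-level noise, gene–gene correlation beyond cluster membership,
and spatial section geometry beyond a rectangle. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under the
stated model, not robustness to every artifact of real tissue data.

## Quality control

`compute_qc_metrics()` counts detected genes (count > 0), total UMIs and the
mitochondrial fraction (0 for empty cells). `filter_nuclei()` retains exactly
the cells with `min_genes <= detected <= max_genes` (closed interval) and
`mito_frac < max_mito_frac` (strict). The species presets encode the standard
inclusion rules: human 500–10,000 genes, < 10% mitochondrial; mouse
400–12,000, < 1%. Boundary semantics are tested on hand-enumerated matrices,
and filtering is verified idempotent and monotone in the thresholds.

`doublet_score()` is a deliberately simplified nearest-neighbor scorer:
artificial doublets (summed random cell pairs) are co-embedded with the real
cells by shared log-CP10K normalization and PCA, and each cell's score is the
fraction of artificial profiles among its `k_neighbors = 30` nearest
neighbors in `n_pcs = 10` dimensions. The parameter-sweep and
homotypic-proportion refinements of the full published detector are omitted:
scoring here is diagnostic (the clustering workflow does not remove called
doublets), and the simplified score separates planted doublets from singlets
with AUROC > 0.95 on synthetic truth.

## Normalization, variable genes, PCA

Normalization is explicit log counts-per-10k:
`ln(1 + 1e4 * count / cell_total)`. A regularized negative-binomial variance
stabilization would be a black-box dependency; the analyses reproduced here
(cluster structure, markers, divergence geometry) are robust to this
substitution, and the substitution is visible and testable.

`select_hvg()` ranks genes by the variance of their log-normalized
expression with a lexicographic tie-break. A binned dispersion statistic
(variance/mean standardized within mean bins) was evaluated first and
rejected: when many informative genes occupy the same mean bins — exactly
the situation the generator creates, where all background genes share one
baseline mean — the within-bin standardization cancels the signal it is
supposed to expose, and planted-marker recovery collapses (~45% versus 100%
for the variance ranking). A trend-standardized variance was rejected for
the same reason: the informative genes themselves define the fitted trend at
high mean.

`run_pca()` z-scores genes (clipped at ±10), decomposes by SVD, and fixes
component signs so the largest-magnitude gene loading is positive —
bit-reproducible embeddings with no RNG.

## Graph clustering and cluster curation

`cluster_graph()` builds the k-NN graph (Euclidean in PC space, `knn_k = 20`,
distance ties broken by cell index), symmetrizes it to a shared-nearest-
neighbor graph weighted by the Jaccard overlap of neighbor lists (pruned
below 1/15), and optimizes modularity with the Leiden algorithm. The
single-species defaults are 16 PCs at resolution 2.0 (the human analysis
setting; the mouse reference analysis used 20 PCs at 3.5). Resolution 2.0
deliberately over-partitions; the curation step below merges what cannot be
told apart. Community detection is seeded and reproducible.

`merge_indistinct_clusters()` formalizes "merge closely related clusters
without distinguishing markers": mutually nearest cluster pairs (centroid
distance in PC space) are merged when a Wilcoxon marker scan in both
directions (`min_pct = 0.25`, `min_diff_pct = 0.25`) yields no gene at
Bonferroni-adjusted p < 0.05, repeating until no pair qualifies. This is one
defensible formalization of a partly judgment-based step, not a claim about
any particular author's manual procedure. Random halves of one population
merge; clusters separated by 20 planted fold-8 markers do not.

`find_markers()` filters candidates by detection rate (`pct_in >= min_pct`,
`pct_in - pct_out >= min_diff_pct`, the `min.pct`/`min.diff.pct` convention),
tests them with a two-sided Wilcoxon rank-sum, and applies Bonferroni
correction over the genes actually tested (the default of the toolkit this
emulates; a false-discovery-rate correction would be less conservative).
The shared `rank_sum_test()` uses exact enumeration of group assignments of
the pooled midranks when both groups have ≤ 8 members — handling ties
exactly — and a tie-corrected normal approximation with continuity
correction otherwise. It matches an independent enumeration oracle on
thousands of random tied instances and `wilcox.test` on its exact and
approximate paths.

`triage_neuronal()` scores each cluster by mean normalized expression over a
neuronal panel (SNAP25, SCN9A, SCN10A, PIEZO2, NEFH) and a non-neuronal
panel (PLP1, MBP, QKI, LPAR1, APOE) and removes clusters whose non-neuronal
score strictly exceeds the neuronal one (ties retain). The non-neuronal
panel is configurable; note that published gene lists of this kind sometimes
carry typos (a "PRP1" is most plausibly PLP1, the canonical myelin gene, and
that is the default here).

## Cross-species co-embedding

`harmonize_genes()` uppercases gene names, resolves case collisions by
keeping the higher-count row (with a warning), and restricts both matrices
to the shared set in identical order. `co_embed()` normalizes each dataset,
z-scores each gene *within dataset* — removing dataset-specific location and
scale, the minimal correction for species offsets — concatenates, and runs a
joint PCA to `n_pcs_joint = 30` (the joint space in which divergences are
computed; joint clustering uses resolution 0.5). Anchor-based integration is
deliberately not re-implemented: the quantity consumed downstream is simply
a common embedding, and `read_embedding_csv()` accepts an externally
computed one (e.g. an anchor-integrated PCA exported from another toolkit)
so real-data users can reproduce the original geometry exactly.

Balance matters in joint embeddings: a much larger reference set dominates
the joint geometry, so `run_cross_species()` subsamples the reference
dataset to the query's size by default (`subsample_b`), a logged, explicit
parameter.

## k-NN Kullback–Leibler divergence

For samples `X ~ P` (n points) and `Y ~ Q` (m points) in d dimensions,
`kl_knn()` computes the classical nearest-neighbor estimator

    D_hat(P||Q) = (d/n) * sum_i log( nu_k(x_i) / rho_k(x_i) ) + log( m/(n-1) )

with `rho_k` the k-th NN distance within the P sample (self excluded) and
`nu_k` the k-th NN distance into the Q sample. `k = 1` by default; `k` is
exposed because the exact estimator variant used in any given published
analysis is rarely stated. The estimator is asymptotically consistent but
can be negative at finite n; negative values are reported raw and clamped
only at the log step (`epsilon_clamp = 1e-6`), preserving diagnosability.
Duplicate points produce zero NN distances, regularized by the smallest
positive distance × 1e-12. The implementation is verified against a
brute-force double-loop reference to 1e-10 and against closed-form Gaussian
divergences (2-D unit shift, KL = 1: mean estimate 0.96–0.98 at
n = m = 5000; the 1-D scale asymmetry KL(P||Q) ≠ KL(Q||P) is reproduced in
direction on every tested seed).

`kl_matrix()` estimates every (query cluster, reference cluster) pair in the
first 30 embedding dimensions, reports clusters under `min_cells = 5` as
missing (never as zero), and applies no symmetrization — the divergence is
directional by definition (the reference species is the reference
distribution). `render_heatmap()` writes the natural-log matrix as CSV and
an unreordered heatmap.

## Spatial neighborhood analysis

`neighborhood_composition()` finds, for every annotated cell and every
neighborhood size n in 1–40, its n nearest annotated neighbors (Euclidean,
self excluded, ties by point index, never crossing section boundaries) and
records the per-center proportion of each label; curves aggregate centers
(mean ± SEM, centers as the independent unit). The random-labeling
expectation around a center is `(count_L − [center is L]) / (N − 1)` within
its section — the minus-one center correction is included although it is
negligible at the map sizes analyzed. The neighbor universe is the annotated
single-positive cells only; unannotated tissue is invisible to the analysis,
matching how such maps are scored.

`clustering_test()` compares, at each n, the per-center proportions of a
target label between same-label and other-label centers with the one-tailed
rank-sum test (alternative: enrichment around same-label centers), and
summarizes significance over the whole range by the **maximum** p across
n = 1–40 — "significant across the complete range" means the worst
neighborhood size is still significant; no further multiplicity correction
is applied, matching how such ranges are conventionally reported.

**Calibration caveat (important).** The per-center Mann–Whitney treats
centers as independent, but neighborhoods of nearby centers share most of
their members, so per-center proportions are positively correlated. The iid
rank-variance formula therefore understates the true null variance of U on
spatial data: on an 800-point uniform map at n = 10 the exact
label-permutation standard deviation of U is ~1.47× the tie-corrected
formula value, and the realized level of the nominal 5% test is ~0.08–0.09
at study-scale maps (it approaches nominal only for maps of ~100 cells).
The parametric route is kept as the primary interface because it is what
analyses of this kind conventionally use, and on genuinely clustered maps
the signal dwarfs the miscalibration (Thomas-process maps give max-p across
n = 1–40 below 1e-6 essentially always). Users who need exact level should
use `permutation_null()`, the label-permutation version with add-one
p-values, which is calibrated by construction at any map size.

## Pipeline, reproducibility, problem sizes

`run_single_species()` chains QC → clustering → optional triage →
re-clustering → merging → markers; `run_cross_species()` chains
harmonization → co-embedding → joint clustering → divergence matrix →
heatmap. Both write CSV artifacts plus a `manifest.json` with per-file MD5
hashes; identical inputs and seeds reproduce identical hashes. Stage
failures carry the stage name. All randomness is funneled through explicit
seeds (simulation configs, clustering seed, integration seed), and seeded
sections restore the caller's RNG state.

The test suite and the acceptance script run at desk scale by design:
1000-cell, 1000-gene simulations for recovery checks; n = m = 5000 for the
Gaussian divergence checks; 800-point maps (the scale of the motivating ISH
analysis) with 1000 null simulations for spatial calibration. These sizes
were chosen to estimate each property with comfortable Monte-Carlo margin
while keeping a full run in minutes on one CPU.

## Known limitations

- No batch/donor integration: multi-preparation datasets are analyzed as a
  single matrix (donor kept as metadata); users needing anchor-based
  integration can import its embedding via the CSV interchange.
- The HVG statistic is variance-based and will favor highly expressed genes
  more than a trend-corrected statistic would on real data with a wide
  mean range.
- The parametric spatial test is anti-conservative on large maps (see
  above); the permutation test is the calibrated alternative.
- KL estimates at `k = 1` carry finite-sample bias (underestimating by a few
  percent at n = 5000 in 2-D); comparisons across cluster pairs of similar
  size are unaffected in rank, which is what the best-match analysis uses.
- UMAP display is out of scope; any embedding viewer can consume the
  exported coordinates.
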