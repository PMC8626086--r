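# drgmap

Clustering, cross-species divergence quantification, and spatial
neighborhood statistics for single-nucleus transcriptomes of sensory
ganglia.

## What it is for

Single-nucleus RNA-seq of dorsal root ganglion (DRG) neurons yields a
gene-by-nucleus UMI count matrix from which transcriptomic cell classes are
derived, compared across species, and related to the spatial arrangement of
cell types in the tissue. `drgmap` implements that workflow end to end for
analysts working with such data (or wanting a fully testable stand-in for
it):

- **QC** — detected-gene and mitochondrial-fraction filtering with the
  standard inclusion rules (human preset: 500–10,000 genes retained,
  < 10% mitochondrial; mouse: 400–12,000, < 1%), plus a nearest-neighbor
  doublet score based on artificial doublets.
- **Clustering** — log-CP10K normalization, variable-gene selection, PCA,
  shared-nearest-neighbor graph + Leiden modularity clustering (default
  16 PCs, resolution 2.0), Wilcoxon marker detection with
  `min.pct`/`min.diff.pct` filters and Bonferroni correction, automatic
  merging of cluster pairs lacking distinguishing markers, and
  neuronal/non-neuronal triage by marker-panel scores.
- **Cross-species comparison** — case-insensitive gene-name harmonization
  (`SCN10A` ↔ `Scn10a`), within-dataset standardization + joint PCA into a
  common 30-dimensional space, joint clustering, and the k-nearest-neighbor
  Kullback–Leibler divergence between every (query cluster, reference
  cluster) pair:

  `D̂(P‖Q) = (d/n) Σᵢ ln( νₖ(xᵢ) / ρₖ(xᵢ) ) + ln( m/(n−1) )`

  where `ρₖ` is the k-th NN distance within the query sample and `νₖ` the
  k-th NN distance into the reference sample, reported as a ln-KL matrix
  and heatmap whose row-wise minima identify each query cluster's best
  cross-species match.
- **Spatial analysis** — for annotated 2-D cell maps (`x_um, y_um, label`),
  the proportion of each cell type among every cell's n nearest neighbors
  (n = 1–40), mean ± SEM curves against the random-labeling expectation, a
  one-tailed Mann–Whitney test of same-label enrichment per n with a
  max-p summary across the range, and an exact label-permutation null.
- **Synthetic data** — a negative-binomial generator with planted clusters,
  markers, library-size variation, mitochondrial content, doublets,
  two-species divergence, and CSR/Thomas-process spatial maps, so every
  claim above is backed by tests with known ground truth.

## Worked example

Simulate a five-cluster dataset and run the single-species pipeline:

```r
library(drgmap)
cfg <- sim_count_config(n_genes = 600, n_cells = 600, n_clusters = 5,
                        marker_genes_per_cluster = 20, marker_fold = 8,
                        doublet_rate = 0, seed = 1)
sim <- simulate_counts(cfg)
res <- run_single_species(sim$counts,
  qc = qc_config(min_genes = 1, max_genes = 10000, max_mito_frac = 1),
  clustering = cluster_config(seed = 1), verbose = TRUE)
table(recovered = res$partition, truth = sim$true_labels)
```

```
[drgmap] raw clustering: 6 clusters (16 PCs, resolution 2)
[drgmap] stage merge_clusters started
         truth
recovered  C1  C2  C3  C4  C5
       C1   0   0 125   0   0
       C2   0   0   0 124   0
       C3   0   0   0   0 119
       C4   0 116   0   0   0
       C5 116   0   0   0   0
```

The raw resolution-2.0 clustering over-splits into 6 clusters; the merge
stage collapses the pair without distinguishing markers, and the final
partition matches the planted truth exactly (labels are arbitrary). The
marker table confirms the planted genes:

```r
head(res$markers[res$markers$cluster == "C1", ], 3)
```

```
     gene log_fold_change pct_in   pct_out   adjusted_p
16 G00056        2.284591  0.736 0.1494737 5.198522e-43
8  G00048        2.233732  0.704 0.1473684 1.874431e-40
17 G00057        2.066649  0.728 0.1768421 4.935464e-39
```

`G00041`–`G00060` were planted as this cluster's markers at fold 8: the top
hits are drawn from that block, detected in ~70% of the cluster versus ~15%
outside, at Bonferroni-adjusted p ≪ 0.05.

For the cross-species half, `simulate_two_species()` produces two matrices
with partially shared marker programs, `run_cross_species()` harmonizes,
co-embeds, and writes the ln-KL matrix; each row's minimum identifies the
paired cluster (see `?kl_matrix` and the methods vignette).

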