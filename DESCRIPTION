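Package: drgmap
Title: Clustering, Cross-Species Divergence, and Spatial Statistics for
    Single-Nucleus Transcriptomes of Sensory Ganglia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible re-implementation of a single-nucleus RNA-seq
    analysis workflow for dorsal root ganglion (DRG) neurons: per-nucleus
    quality control and doublet scoring, log-normalization, highly variable
    gene selection, PCA, shared-nearest-neighbor graph clustering, Wilcoxon
    marker detection with min.pct/min.diff.pct filters, merging of clusters
    lacking distinguishing markers, neuronal/non-neuronal triage,
    cross-species gene-name harmonization and joint embedding, k-nearest
    neighbor Kullback-Leibler divergence estimation between cluster
    distributions in PC space, and neighborhood-composition analysis of
    spatially mapped cell types with one-tailed Mann-Whitney tests. A
    negative-binomial synthetic-data generator with planted cluster, doublet
    and spatial structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    pheatmap,
    grDevices,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
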