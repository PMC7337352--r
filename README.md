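# wavemap

Geometric clustering of synchronized time-series gene-expression data.

Synchronized time-course experiments — metabolic cycles, cell cycles,
dose–time toxicology panels — produce thousands of gene profiles whose
relationships are periodic, phase-shifted and noisy. `wavemap` is for
computational biologists who want to recover that structure without
pre-filtering the gene set: it encodes every profile as Haar wavelet
coefficients, builds a cosine similarity graph sparsified by k-symmetric
nearest neighbours, turns it into the transition matrix of a Markov chain
over genes, and eigendecomposes that chain into a low-dimensional
diffusion-map embedding. On the embedded genes it offers Bregman k-means
(k-means++ initialization, restart-based model selection), non-negative
matrix factorization and affinity propagation, a per-gene *local dimension*
score (a pointwise count of the principal axes a gene's neighbourhood
needs — low for tightly co-regulated genes, near the ambient dimension for
noise), a filtered Delaunay triangulation whose edges carry correlation
signs and p-values, and a hypergeometric enrichment test for user-supplied
annotations. Every run is recorded into a plain-text scenario that replays
byte-identically.

## The core model

For genes `i, j` with Haar coefficient vectors `u_i, u_j` (n = 64):

- similarity `W_ij = (1 + cos θ_ij) / 2 ∈ [0, 1]`, sparsified by
  k-symmetric nearest neighbours (k = 10);
- Markov chain `N = D⁻¹ W` (rows sum to 1); right eigenpairs
  `λ_1 = 1 > λ_2 ≥ …` give diffusion coordinates
  `y_i = (λ_2 v_2(i), λ_3 v_3(i), λ_4 v_4(i))`;
- Bregman k-means minimizes `Σ_i d(y_i, c_{label(i)})` by Lloyd iterations
  (the centroid under any Bregman divergence is the mean), best of 5
  k-means++ restarts, elbow over `K = 3..15`;
- Delaunay edges (i, j) are scored by the Pearson correlation of the raw
  profiles and its two-sided t-test p-value on `T − 2` df; edges with
  `p ≤ 0.001` are the significant co-regulation network.

## Worked example

```r
library(wavemap)

# a metabolic-cycle-like design: 3 phase groups x 50 genes + 150 aperiodic,
# 36 time points across 3 cycles of 300 minutes, noise sd 0.2
sim <- generate_synthetic(synthetic_spec(seed = 1))
sim$dataset
#> expression_dataset: 300 genes x 36 time points (0..291.667 min)

res <- run_pipeline(sim$dataset, out_dir = "out", k = 4, seed = 1)
res$clustering
#> clustering_result (bregman_kmeans): K=4, sizes 149/50/50/51, potential 0.0186353
res$triangulation
#> triangulation_result: 1911 edges, 1337 significant at p <= 0.001
#>   (mean length 0.002868 vs 0.03607 overall)

sentinel_report(res$clustering$labels, sim$sentinels)
#>      set  n majority_cluster correct collision
#> 1 group1 10                4     100         0
#> 2 group2 10                2     100         0
#> 3 group3 10                3     100         0

mclust::adjustedRandIndex(res$clustering$labels, sim$labels)
#> 0.99
```

Reading the output: the four clusters recover the three planted phase groups
(50/50/51 genes) and the aperiodic background (149), with adjusted Rand
index 0.99 against the ground truth. Each group's ten noise-free sentinel
genes land in a single cluster (`correct = 100`, `collision = 0`).
Significant Delaunay edges are an order of magnitude shorter than the
average edge — strongly correlated genes sit close together on the manifold.
`out/` now holds `manifold.tsv` (coordinates), `clusters.tsv` (labels and
local dimensions), `edges.tsv` (the scored network), `scenario.txt` (the
replayable record) and `run.log`.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/wavemap.R simulate --seed 1 --out expr.tsv --truth truth.tsv
Rscript inst/cli/wavemap.R run --expression expr.tsv --k 4 --seed 1 --out-dir out
Rscript inst/cli/wavemap.R replay --scenario out/scenario.txt --out-dir out2
```

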