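---
title: "Methods: wavelet features, diffusion maps and geometric clustering of expression time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet features, diffusion maps and geometric clustering of expression time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`wavemap` clusters synchronized time-series gene-expression data by combining
a principled time-series representation (Haar wavelets), nonlinear manifold
learning (a diffusion map over a gene-similarity Markov chain), and a battery
of geometric post-processing tools (Bregman k-means, NNMF, affinity
propagation, filtered Delaunay networks, local-dimension scores). This
vignette explains each model, the parameters that matter, and the design
choices made where more than one reasonable option existed.

## The model, stage by stage

### 1. Haar wavelet encoding

Each gene's profile, measured at `T` (possibly irregular) time stamps, is
linearly resampled onto a uniform grid of `n = 64` points spanning its time
course and multiplied by the `n × n` *orthonormal* Haar matrix
(`encode()`). The orthonormal convention makes the transform an isometry:
`sum(coeffs^2)` equals the energy of the resampled signal exactly (Parseval),
and the inverse transform reconstructs it to machine precision. Resampling by
piecewise-linear interpolation is our choice for bridging the gap between
measured lengths such as `T = 36` or `T = 17` and the dyadic length the
transform needs; padding or truncation would distort either the period
structure or the cycle count. Encodings with `n = 64` and `n = 32` give
downstream similarities agreeing to a few hundredths for smooth profiles, so
the default is not delicate. Genes are not standardized before encoding — the
cosine similarity used next is already scale-invariant — but
`center_genes = TRUE` removes each gene's mean first.

### 2. Cosine similarity and k-symmetric nearest neighbours

The gene–gene similarity is the cosine of the angle between wavelet vectors,
affinely mapped to `[0, 1]`:

    W[i, j] = (1 + cos θ_ij) / 2,

so 1 means identical direction, 0 anti-parallel, 0.5 orthogonal. The affine
map is the only monotone choice hitting both stated endpoints. The dense
matrix is sparsified by *k-symmetric nearest neighbours* (`k = 10`): keep
entry (i, j) if j is among the k largest similarities of row i *or* vice
versa (the logical-or keeps the matrix symmetric); ties at the k-th value
break deterministically toward the lower gene index. A heat-kernel
alternative `exp(-||u - v||² / 2σ²)` is available via
`build_W(method = "heat")`.

### 3. Markov chain and diffusion-map embedding

The sparse similarity graph is normalized into a row-stochastic matrix `N` —
the transition matrix of a Markov chain whose states are genes. Three
normalizations are implemented: plain `markov` (`D⁻¹W`, the default),
`symmetric` (`D^-1/2 W D^-1/2`, row-rescaled), and `sinkhorn` (alternating
row/column scaling to a doubly stochastic matrix, tolerance 1e-8, at most
10,000 sweeps). Right eigenvectors of `N`, ordered by descending eigenvalue,
give the embedding; the trivial constant eigenvector (eigenvalue 1) is
discarded and coordinate `j` is `λ_{j+1} v_{j+1}` — the diffusion-map
scaling, which damps axes with small spectral gap. Eigenvector signs are
fixed by making the largest-magnitude entry positive, so runs are
reproducible. `d = 3` matches the tool's natural visualization space.

When the planted groups are clean, the k-NN graph can disconnect; the chain
is then reducible, eigenvalue 1 has multiplicity equal to the number of
components, and each component collapses to (nearly) one point in the
embedding. The pipeline warns but proceeds: clustering on indicator-like
coordinates is trivially correct, and the Delaunay stage resolves coincident
points by jitter (below).

### 4. Local dimension

For every gene we take its `k_nb = 30` nearest neighbours in the embedding
(plus itself), estimate the covariance of the neighbourhood *in wavelet
feature space*, and report the smallest number of principal axes whose
cumulative variance fraction reaches `τ = 0.95`, linearly interpolated
between the bracketing integers for a continuous score. Scores are measured
in feature space deliberately: a gene's neighbourhood may need far more axes
than the 3-D embedding (tightly co-regulated genes score near 1–3; genes
embedded among unstructured neighbours approach the ambient feature
dimension).

Because the neighbourhood sample size (31–61 points) is comparable to the
feature dimension, raw sample covariance eigenvalues over-disperse
(Marchenko–Pastur), which biases the axis count *low* — an isotropic 10-D
cloud scores about 8.9 instead of near 10. We therefore shrink the
off-diagonal covariance entries by their estimated noise fraction
(Schäfer–Strimmer-style shrinkage, standard for small-sample expression
covariances). Shrinkage intensity is data-driven per neighbourhood: near 0
when correlations are real (a 1-D line in 10-D scores 0.97; a clean 2-D
plane 1.9–2.2 whether axis-aligned or rotated), near 1 for pure noise (the
10-D cloud scores 9.3). The estimator's neighbourhood definition and
interpolation rule are package choices; the underlying idea — a pointwise
count of locally needed principal axes — is fixed.

### 5. Clustering battery

**Bregman k-means** (`bregman_kmeans()`): Lloyd batch iterations under
squared Euclidean (default) or generalized Kullback–Leibler divergence. For
every Bregman divergence the optimal centroid is the arithmetic mean, so the
update is shared; the assignment-step potential is non-increasing and
iteration stops when labels stabilize (cap 300). Initialization is
k-means++ (Arthur–Vassilvitskii). The recommended protocol is 5 restarts,
keeping the best potential. Emptied clusters are re-seeded at the point
farthest from its center. KL requires positive coordinates; a minimum shift
(`x - min + 1e-6`) is applied with a message when needed.

**Model selection** (`selection_curve()`): for each `K` in `3..15` the mean
and standard deviation of the restart potentials are recorded. The elbow is
the `K` maximizing the ratio of the mean-potential drop *into* `K` over the
drop *out of* `K` — the "sharp decrease before, mild decrease after"
criterion. On four planted blobs this selects `K = 4`; on real data the
curve should be inspected, since a shoulder can justify a nearby `K` when it
aligns better with external knowledge.

**NNMF** (`nnmf_cluster()`): Lee–Seung multiplicative updates for
`min ||X − FH||²` with nonnegativity; the objective is non-increasing at
every sweep. The factorized matrix is the sparsified similarity matrix
(nonnegative by construction) rather than the manifold coordinates, which
may be negative. Labels are per-gene argmax loadings. Initialization is
deterministic NNDSVD (positive/negative parts of leading singular vectors,
zeros replaced by the matrix mean): purely random starts can lock
multiplicative updates into poor local minima even on exactly factorable
inputs, whereas NNDSVD recovers such factorizations to numerical zero.

**Affinity propagation** (`affinity_propagation()`): Frey–Dueck
responsibility/availability message passing with damping (default 0.9),
preference defaulting to the median off-diagonal similarity, convergence
declared after 50 sweeps of a stable exemplar set. A deterministic
tie-breaking perturbation (1e-10 of the similarity spread) replaces random
noise so results are reproducible; the output is invariant to a constant
shift of similarities and preference.

### 6. Filtered Delaunay triangulation

The 3-D Delaunay triangulation of the embedding is computed by an
incremental Bowyer–Watson algorithm written for this package (no suitable
triangulation library for 3-D is declared as a dependency). Points are
centered and scaled to unit radius first — the complex is invariant under
that affine map and the circumsphere tests stay well conditioned. The
circumsphere solver tries all four vertices as the elimination reference and
keeps the best-conditioned one, which is what makes sliver tetrahedra (three
nearly coincident vertices plus one distant — routine when a graph component
collapses) solvable. Degenerate inputs (duplicates, coplanarity) receive a
deterministic quasi-random jitter of 1e-6 of the coordinate range and one
retry; 1e-6 is small enough to be statistically invisible but large enough
that double-precision circumsphere tests can discriminate points within a
collapsed component blob. Each edge is annotated with the Pearson
correlation `r` of the two genes' *raw* expression profiles (edge colour
should reflect the biologist-facing notion of co-regulation, not the wavelet
representation), a two-sided p-value from the t statistic on `T − 2` degrees
of freedom, and the correlation sign. Edges with `p ≤ 0.001` are flagged
significant; no multiple-testing correction is applied by default (an
optional Benjamini–Hochberg switch exists) because the raw threshold is the
quantity of interest in the summary statistic: on structured data the mean
significant-edge length is far below the mean edge length, confirming that
strongly correlated genes sit close on the manifold.

### 7. Enrichment, scenarios, CLI

`enrich()` is an upper-tail hypergeometric test of term over-representation
within a cluster against a user-supplied gene→term table, with
Benjamini–Hochberg q-values per cluster. Every pipeline run appends each
operation, its full parameter map (seed included) and MD5 digests of files
read/written to a plain-text scenario (`scenario.txt`); `scenario_replay()`
re-executes the run and reproduces `clusters.tsv`, `manifold.tsv` and
`edges.tsv` byte for byte, warning (or failing, in strict mode) if an input
file's digest has drifted. A thin command-line interface
(`inst/cli/wavemap.R`) exposes each stage as a subcommand.

## The synthetic study design

`generate_synthetic()` emulates a metabolic-cycle-like experiment: periodic
phase groups `a·sin(2π·c·t/total + φ_g) + ε` with group phases spread
uniformly on the circle, per-gene amplitudes uniform in `[1, 2]`, noise
`ε ~ N(0, 0.2²)`, plus a population of aperiodic genes built from
standardized smoothed Gaussian random walks. The default design — 3 groups ×
50 genes + 150 aperiodic genes, 36 time points across 3 cycles of a
300-minute course — mirrors the structure of classic yeast metabolic-cycle
datasets (three phase-shifted sentinel groups, roughly a third of genes
periodic) at a desk-friendly scale. Time stamps are `(0:(T−1))·total/T`, so
the cycle is an exact number of sampling steps and noiseless profiles repeat
across cycles to 1e-12. The first 10 genes of each group are generated
noise-free, playing the role of experimentally validated sentinel markers;
`sentinel_report()` scores how a clustering co-assigns them (percent in the
majority cluster, and the complementary "collision" percentage).

What the generator does *not* emulate: probe-level noise structure
(heteroscedastic, intensity-dependent), missing values, amplitude drift
across cycles, non-sinusoidal wave shapes, and dose × time designs (only a
single time factor). Passing the end-to-end tests therefore demonstrates
that the pipeline recovers phase structure under additive Gaussian noise,
not that it is robust to every artefact of microarray or sequencing data.

## Numerical choices and degenerate inputs

- Missing expression values: `drop_gene` (default) or linear `interpolate`
  along the gene's own time course; counts are logged.
- Zero feature rows (cosine undefined) and isolated graph rows abort with
  the offending gene names.
- Sinkhorn non-convergence (tolerance 1e-8 within 10,000 sweeps) is an
  error reporting the residual.
- Complex eigenvalues (possible for non-reversible normalizations) are
  truncated to real parts with a warning.
- k-means empty clusters re-seed at the farthest point; k-means++ refuses
  `K` above the number of distinct points.
- Delaunay degeneracy: deterministic jitter then error, as described above.
- Zero-variance expression profiles drop their Delaunay edges with a
  warning; p-values are floored at the smallest positive double.

## Problem sizes used in the test suite

End-to-end checks run the default 300-gene design (about 2 s per full
pipeline on one core); unit tests use a 100-gene variant. Eigen-solver
agreement is checked on 8-gene graphs against an independent
symmetric-conjugate route; Delaunay output is verified against a brute-force
empty-circumsphere oracle on 20-point sets; affinity propagation is
cross-checked against an independent reference implementation on a 60-point
three-blob fixture.

## Known limitations

- The Bowyer–Watson triangulator targets the pipeline's 3-D embeddings;
  it is exact for points in general position but relies on jitter rather
  than exact arithmetic for degeneracies, and its incremental construction
  is not tuned beyond a few thousand points.
- Eigendecomposition is dense; tens of thousands of genes fit comfortably
  in memory, but very large panels would warrant a sparse/iterative solver.
- The local-dimension score depends on the neighbourhood size `k_nb`;
  values are comparable within one run, not across runs with different
  `k_nb`.
- Affinity propagation on the similarity graph inherits its known
  sensitivity to the preference parameter; the median default reproduces
  moderate cluster counts but should be scanned when cluster number matters.
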