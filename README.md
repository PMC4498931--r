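# paretoscope

Pareto task inference for single-cell expression data: find the polytope
that encloses a cloud of cells in gene-expression space, test whether that
geometry is statistically meaningful, and characterize what each vertex is
for.

## The idea

Trade-off theory predicts that cells juggling several tasks arrange
themselves inside a low-dimensional polytope — a line for two tasks, a
triangle for three, a tetrahedron for four — whose vertices (*archetypes*)
are the expression profiles optimal for a single task. Cells near a vertex
are specialists; cells in the middle are generalists. `paretoscope`:

1. **fits** k-vertex polytopes by principal convex hull analysis (PCHA),
   the archetypal-analysis factorization
   `min ||X - XCS||²` with `S ≥ 0, 1ᵀS = 1` and
   `C ≥ 0, 1-δ ≤ 1ᵀC ≤ 1+δ`, solved by a compiled projected-gradient
   method with exact simplex projections and a monotone line search;
2. **selects k** from the elbow of the explained-variance-versus-k curve,
   cross-checked by PCA dimensionality against column-shuffled data;
3. **tests significance** against shuffled nulls that keep every gene's
   marginal distribution but destroy correlations, using explained
   variance and the t-ratio (polytope volume / convex-hull volume in the
   first k−1 PCs);
4. **characterizes archetypes** by leave-one-out binned enrichment
   (equal-mass bins by distance from each archetype, first-bin maximality
   plus a one-sided Wilcoxon rank-sum test), 2-D kernel-smoothed
   enrichment maps, and gene-set enrichment with BH-FDR and bootstrap
   robustness filtering;
5. **quantifies robustness and shape**: bootstrap ellipses for archetype
   positions, per-cell description stability versus clustering/PCA, the
   archetype splitting tree, and the uniformity ratio ρ (≈1 for a filled
   continuum, ≫1 for discrete clusters).

Modality-specific preprocessing covers single-cell qPCR Ct matrices
(detection-ceiling handling, (30−Ct) flip, centering, low-expression
filtering), mass cytometry (duplicate-channel averaging, arcsinh with
cofactor 5), and RNA-Seq counts (per-cell downsampling without
replacement, log2, top-variance gene selection).

## Worked example

```r
library(paretoscope)

# cells sampled uniformly inside a tetrahedron, 2% additive noise
dat <- sample_polytope(synthetic_spec(k = 4, ambient_dim = 3,
                                      n_cells = 400, noise_sd = 0.02,
                                      seed = 1))

ec <- ev_curve(dat$matrix, k_max = 8, seed = 1)
ec
#> Explained variance by number of archetypes:
#>  k     ev elbow_dist
#>  2 0.2200     0.0000
#>  3 0.5076     0.1579
#>  4 0.9658     0.4850
#>  5 0.9764     0.3682
#>  6 0.9854     0.2497
#>  7 0.9871     0.1240
#>  8 0.9905     0.0000
#> k* (elbow) = 4

sig <- significance_tratio(dat$matrix, k = 4, m = 100, seed = 1)
sig
#> t_ratio shuffle test, k = 4: observed = 0.5306, p < 0.01 (m = 100)

fit <- pcha_fit(dat$matrix, k = 4, delta = 0.5, seed = 1)
round(fit$archetypes[, 1:3], 2)
#>    dim_1 dim_2 dim_3
#> A1  0.53 -0.21 -0.34
#> A2 -0.59 -0.24 -0.33
#> A3 -0.01  0.72  0.02
#> A4  0.03 -0.20  0.73
```

Reading the output: the explained-variance curve saturates after k = 4, so
the elbow picks a tetrahedron; its t-ratio beats all 100 column-shuffled
datasets (p below the 1/m resolution of the test), and the four fitted
vertices sit near the true simplex corners (the generator's vertices are a
unit-edge regular simplex). `enrich_1d()` would then report which features
peak in the cells closest to each vertex.

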