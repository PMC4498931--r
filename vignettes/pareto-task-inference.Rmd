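---
title: "Pareto task inference for single-cell expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto task inference for single-cell expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoscope)
```

## The model

Evolutionary trade-off theory predicts that cells balancing several tasks
arrange themselves, in gene-expression space, inside a low-dimensional
polytope — a line for two tasks, a triangle for three, a tetrahedron for
four. The vertices ("archetypes") are the expression profiles that would be
optimal for one task alone; a cell's position inside the polytope encodes
its mixture of tasks. `paretoscope` tests whether a cells-by-features
expression matrix is consistent with this picture, locates the archetypes,
and asks which genes and gene sets characterize each of them.

The polytope is fitted by principal convex hull analysis (PCHA), the
archetypal-analysis factorization

$$\min_{C,\,S}\ \lVert X - XCS\rVert_F^2
\quad\text{s.t.}\quad S \ge 0,\ \mathbf{1}^\top S = \mathbf{1},\quad
C \ge 0,\ 1-\delta \le \mathbf{1}^\top C \le 1+\delta ,$$

where $X$ is the feature-major data matrix, the columns of $C$ write each
archetype as a weighted average of cells (so $Z = XC$), and the columns of
$S$ write each cell as a convex mixture of archetypes. With $\delta = 0$
archetypes cannot leave the convex hull of the data; $\delta > 0$ lets them
sit slightly outside it, which matters because a finite sample rarely
reaches the true vertices. We follow the convention of using $\delta = 0$
wherever explained variance or significance is computed, and $\delta = 0.5$
when archetype positions are characterized (enrichment, reporting).

### The solver

`pcha_fit()` runs an alternating projected-gradient method (compiled, via
RcppArmadillo). Each half-step takes a gradient step in $S$ or $C$ and then
projects back onto the feasible set using the exact Euclidean projection
onto the simplex (sort-based); for $C$ the column sum is pulled back into
$[1-\delta, 1+\delta]$ only when violated. A monotone backtracking line
search accepts a step only if the objective does not increase, so the
objective trace is non-increasing by construction — this is asserted on
every fit. Step sizes halve on failure and are allowed to double between
iterations, which prevents the stalls that a fixed learning rate produces
on flat regions of the objective.

Initialization is a greedy max-min ("furthest sum") selection of k cells,
repeated over `n_restarts` (default 5) random starting cells, keeping the
best objective. Convergence is declared when the relative objective change
falls below `tol` (default 1e-6) before `max_iter` (default 2000)
iterations. Archetypes are reported in a canonical order (projection on
the data's first principal axis, ties by the second) so that repeated runs
are comparable.

### Explained variance

Two definitions are implemented. The per-point statistic

$$EV = \frac1N \sum_{n=1}^{N} \left(1 - \frac{\lVert p_n - s_n\rVert}
{\lVert p_n\rVert}\right),$$

with $s_n$ the polytope reconstruction of cell $p_n$, is the default
(`"as_printed"`) and is what the explained-variance curve and the EV-based
shuffle test report. The conventional SSE ratio
$1 - \lVert X - XCS\rVert_F^2 / \lVert X\rVert_F^2$ (`"sse_ratio"`) is what
the optimizer minimizes and is also exposed. The per-point form divides by
$\lVert p_n\rVert$, so a cell lying exactly at the origin (the grand mean,
since data are centered) has no defined relative error; such cells are
excluded from the mean with a warning rather than silently propagating an
infinity.

## Choosing the number of archetypes

`ev_curve()` fits every $k$ in $2..k_{max}$ (default 11) with $\delta = 0$
and finds the elbow: the point of the $(k, EV)$ curve most distant, in
perpendicular distance with both axes unscaled, from the straight line
through the first and last points. Ties resolve to the smallest $k$. The
elbow is insensitive to the choice of $k_{max}$ over a broad range on
polytope-shaped data.

`pca_dimensionality()` gives an independent estimate of the effective
dimensionality $D$ (a $k$-vertex polytope is $(k-1)$-dimensional): the
variance explained by each principal component of the real data is
compared with the mean and SD of the same quantity over column-shuffled
data (default 100 shuffles), and $D$ is the number of leading components
that stay above the shuffled mean plus one SD. "Comes within one SD" could
also be read as entering the band mean ± 1 SD; the stricter
above-mean-plus-SD crossing is the default and the band rule is available
via `rule = "band"`.

## Significance against shuffled data

All null models permute each feature's values independently across cells
(`shuffle_matrix()`), preserving every marginal exactly while destroying
the correlations that create geometric structure.

Two statistics are offered. The EV test refits the polytope on each of $m$
shuffles and reports the fraction with EV at least that of the real data.
The t-ratio test projects the data onto their first $k-1$ principal
components, takes the ratio of the $\delta=0$ polytope volume to the
convex-hull volume of the projected data, and compares it with shuffles,
each re-projected onto its own principal components so the null sees the
full pipeline. We store the ratio as polytope/hull, which lies in $(0,1]$
and increases as the data become more polytope-like; the upper tail
(shuffles with a ratio at least as large as the data's) then matches the
statement "the bigger the t-ratio, the more similar the data to a
polytope". The opposite orientation merely inverts the ratio and, with the
tail kept consistent, gives identical p-values. The t-ratio test is the
more stringent of the two on continuum-like data and is the default in
`polytope_scan()`.

p-values are the plain empirical fraction with no +1 correction; a zero is
reported as "< 1/m". No multiplicity correction is applied across $k$.
Hull volumes are computed by an incremental (beneath-beyond) convex-hull
construction written for this package, exact for full-dimensional point
sets in the small dimensions used here ($k-1 \le 4$); polytope volumes use
the simplex determinant formula directly.

## Characterizing archetypes

### Leave-one-out 1D enrichment

Testing whether a gene is high near an archetype, using archetypes that
were fitted with that gene included, is circular. `enrich_1d()` therefore
removes each feature, refits the archetypes in the remaining
$(d-1)$-dimensional space (warm-started from the full fit, which suppresses
restart stochasticity and keeps the displacement tiny —
`loo_displacement_summary()` reports it), bins cells into equal-mass bins
(default 10) by distance from each archetype, and calls the feature
enriched when its mean expression is maximal in the closest bin *and* a
one-sided Wilcoxon rank-sum test of the closest bin against all remaining
cells is below `p_threshold` (default 0.001, deliberately strict because
every feature is tested against every archetype). When the cell count does
not divide evenly, the larger bins are the nearest ones. The rank-sum
comparison pools all non-first bins by default — pooling maximizes power
and the one-sided alternative matches the maximality requirement — but
per-bin comparison and two-sided alternatives are exposed for sensitivity
analysis.

### 2D enrichment maps

`enrich_2d()` draws the classic sanity-check picture: cells on the first
two principal components (computed without the tested feature, as are the
archetypes), with the feature smoothed by an anisotropic Gaussian kernel.
Bandwidths follow Silverman's rule of thumb per axis,
$h_j = (4\sigma_j^5 / 3N)^{1/5}$. The smoothed ratio
$\sum_i m_i K_i(x) / \sum_i K_i(x)$ is multiplied by a Hill function of the
kernel density, $D^n/(\kappa^n + D^n)$ with $\kappa = 8$, $n = 2$, which
zeroes the map where there are effectively no cells — otherwise the ratio
is dominated by whichever single cell is least far away. The map's argmax
and its distance to each archetype are returned.

### Gene sets

`enrich_gene_sets()` scores each set per cell as the mean centered
expression of its measured genes (the simplest score consistent with
"genes of this program are jointly high"; a hypergeometric overlap test
against the significant-gene list is a reasonable alternative but needs a
gene-level significance call first). The first-bin-maximal + rank-sum
machinery is reused, the FDR is controlled by Benjamini-Hochberg across
all (set, archetype) pairs at q = 0.1, and a set is only *reported* when
it is significant at the same archetype in at least 80% of 100 bootstrap
refits — enrichment that does not survive resampling is not worth
reporting. GMT is the interchange format.

## Robustness

`bootstrap_archetypes()` resamples cells with replacement, refits, and
matches each replicate's archetypes back to the full-data fit by optimal
assignment (Hungarian method; an exact permutation search is the fallback
and the test oracle). Each archetype then owns a cloud of positions whose
SDs along the cloud's top three principal axes, divided by the distance of
the cloud center from the origin of the centered data, are its error
estimates. This normalization presumes centered data (the origin is the
mean expression profile); on uncentered data the denominator would be
arbitrary.

`description_stability()` quantifies the claim that archetype descriptions
are more stable than cluster assignments on continuum-like data: across
bootstrap replicates, every original cell is re-described as a convex
mixture of the replicate's archetypes, as its projection on the
replicate's principal components, or as the centroid of its assigned
cluster (k-means, average-linkage hierarchical clustering, or a 2x2
self-organizing map). The per-cell normalized SD of these approximations
across replicates, and the fraction of cells above 0.3, are reported per
method. On data that fill a polytope, cluster boundaries cut through a
continuum and centroid descriptions jump; archetype mixtures move little.

`archetype_tree()` fits increasing $k$ and links each archetype to its
nearest parent at $k-1$, showing how vertices split as the description is
refined.

## The synthetic generator

`sample_polytope()` draws cells as $W Z + \varepsilon$: archetypes $Z$ a
regular simplex with unit edge (by default; any affinely independent set
is accepted), weights $W$ with rows from a symmetric Dirichlet($\alpha$),
and isotropic Gaussian noise. $\alpha$ is the single knob spanning the
continuum-versus-clusters axis: $\alpha = 1$ is the uniform-filling regime,
$\alpha \ll 1$ (via `sample_clustered()`) produces vertex-clumped,
cluster-like clouds. The default is $\alpha = 1$ and zero noise — uniform
sampling from the unit simplex, the reference condition for the
power-versus-sample-size behavior of the significance tests; recovery
checks add noise with SD 2% of the edge length. Planted enriched features
decrease linearly with distance to a target archetype with SD-0.3 noise
around an effect size of one edge length, and pure-noise features can be
appended.

`sample_enrichment_dataset()` is the enrichment benchmark: 400 cells, 60
features of which 8 are geometry coordinates, 40 are planted enriched
features (10 per archetype of a tetrahedron) and 12 are pure noise. The
composition is deliberately dominated by informative features, mirroring
panel-based single-cell studies in which most measured genes were selected
for being developmentally informative; a benchmark dominated by pure-noise
features would degrade the distance ordering for every method, not just
this one. Note that in this benchmark the geometry coordinates are
themselves legitimately archetype-enriched (any linear coordinate is
maximal at some vertex), so false-positive counts are taken over the
pure-noise features.

What the generator does not emulate: qPCR censoring mechanics (all/none
bimodality at the detection limit), CyTOF spillover, count sparsity, or
correlated technical noise. Passing tests on these fixtures shows the
geometry, testing and enrichment machinery work as specified; it does not
by itself validate biological conclusions on any real dataset.

## Preprocessing conventions

* qPCR: Ct values above the detection ceiling (default 30 cycles) and
  missing entries are set to the ceiling (undetected), the scale is flipped
  to `ceiling - Ct` so larger means more expressed, and features are
  mean-centered. Missing entries are treated as undetected because the
  technology's characteristic failure mode is all-or-none dropout, not
  missing-at-random.
* Low-expression filtering removes a fixed fraction (default 10%) of cells
  first, then features, with totals recomputed after the cell removal and
  measured on the pre-centering scale (centering destroys totals; the
  pre-centering matrix is carried along for exactly this purpose). `floor`
  converts fractions to counts by default; `round` is exposed because
  published cell counts are sometimes consistent with either.
* Multiple qPCR primers for one gene are kept as separate features;
  duplicate CyTOF channels for one protein are averaged per cell before
  the arcsinh transform (cofactor 5), because the latter measure the same
  molecule on the same scale while primer pairs need not.
* RNA-Seq: per-cell downsampling without replacement to a fixed depth
  (default 400 molecules; cells below it are dropped), then `log2(x+1)`
  and centering. Each cell draws from an RNG substream derived from the
  seed and the cell's index, so results do not depend on cell order.
  Sparse matrices are first reduced to the top-SD features (default 500).

## Numerical choices and degenerate inputs

* All-constant matrices and k > n are rejected before fitting; non-finite
  values are rejected.
* Convex hulls require full-dimensional input; rank-deficient point sets
  are rejected with the detected rank (`uniformity_rho()` instead projects
  to the rank and matches the ball volume to that dimension, with a
  warning).
* A collinear-archetype polytope has volume 0 and yields t-ratio 0 with a
  warning rather than an error, since shuffled nulls can produce it.
* Neighbor counts in the uniformity ratio exclude the focal point; the
  self-count is an n-independent bias that would push rho toward 1.
* Uniform sampling inside a hull uses bounding-box rejection against the
  facet planes; for the elongated hulls of strongly clumped data this is
  slower but exact.
* Equal-mass-bin ties (equal distances) break by cell index, making binning
  deterministic.

## Problem sizes used in the test suite

The suite exercises vertex recovery at 60,000 cells (where hull-corner
sampling error is a few percent of the edge), test calibration with 200
replicate datasets at m = 50 shuffles, power curves over n = 10..160 at
m = 100, enrichment recovery on twenty 400-cell benchmark replicates, and
bootstrap ensembles of 30-100 replicates; these sizes make each property
measurable with comfortable margins while keeping a full run of the suite
in the minutes range on one core.

## Known limitations

* PCHA finds a local optimum; restarts mitigate but do not eliminate this.
  On data with no polytope structure different restarts can return quite
  different vertex sets — which is precisely what the shuffle tests detect.
* With $\delta > 0$ the objective is flat once the polytope encloses the
  data, so vertex positions inherit some path dependence from the
  optimizer; bootstrap ellipses are the honest way to report that
  uncertainty.
* The hull construction is exact but not engineered for dimensions beyond
  ~6 or adversarial degeneracies; the t-ratio pipeline only ever uses
  $k - 1 \le 4$ dimensions.
* Small gene sets and few measured set genes make the mean-score noisy;
  sets with no measured genes are dropped with a warning rather than
  scored.
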