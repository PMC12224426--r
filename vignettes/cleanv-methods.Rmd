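---
title: "Methods: spatial-extent inference for variance components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-extent inference for variance components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `cleanv`, the
conventions and defaults the implementation commits to, and the places
where the design was genuinely open. It states no empirical result beyond
what the package's test suite and `scripts/acceptance.R` themselves
compute.

## The generative model

For `N` images observed at `V` surface vertices, the data at vertex `v`
follow

$$y(v) = X\beta(v) + r(v) + \epsilon(v), \qquad
  r(v) \sim \mathcal{N}\!\left(0,\; \theta^2(v)\, K\right),$$

with the residual image of subject $i$ decomposed as
$\epsilon_i = b_i + \delta_i$,

$$b_i \sim \mathcal{N}\!\left(0,\; \sigma^2 \Phi(\phi, D)\right), \qquad
  \delta_i \sim \mathcal{N}\!\left(0,\; \tau^2 I_V\right),$$

all independent. $K$ is the study-design relatedness matrix: same-subject
blocks of ones for test–retest designs, coefficients 1 (MZ) and 0.5 (DZ)
within twin pairs, or an arbitrary positive-semidefinite genetic
relationship matrix. $\Phi(\phi, D) = \exp(-\phi D)$ is the exponential
spatial autocorrelation function (SACF) over the geodesic distance matrix
$D$ (mm); $\phi$ has units 1/mm. The hypothesis of interest is global:
$H_0: \theta^2(v) = 0$ for every $v$. Under the vertex-level (non-spatial)
model the effect size is the intraclass correlation / heritability ratio
$\theta^2(v) / (\theta^2(v) + \tau^2(v))$, which
`estimate_effect_size()` reports descriptively via method-of-moments.

Assumptions worth keeping in mind: the SACF is stationary and isotropic in
geodesic distance, shared by all images; the between-image effect $r(v)$ is
independent across vertices given $\theta^2(v)$; and Gaussianity throughout.
Violations of stationarity or isotropy affect power, not validity — the
inference is permutation-based and only requires exchangeability of images
under $H_0$.

## Geodesic distances and neighborhoods

Distances are edge-weighted shortest paths on the mesh graph (edge weight =
Euclidean edge length), computed with Dijkstra's algorithm via `igraph`.
This overestimates exact polyhedral geodesics by a bounded factor on
well-shaped triangulations, which is immaterial here: distances are only
thresholded at integer-mm radii. Users with exact geodesics (e.g., from a
heat-method solver) can supply them via `surface_from_distances()`.

Masked vertices (e.g., the medial wall) are removed from the graph before
the computation, so they never enter any neighborhood, statistic, or
maximum. Neighborhoods $N_r(v) = \{u : d(v, u) \le r\}$ are precomputed
once per (distances, radii) pair as sparse indicator matrices and reused
across all permutations; radius 0 is always included so the raw vertex
statistic participates in the adaptive maximization. The default radius set
is $\{0, 1, \dots, 20\}$ mm with unit spacing; `rmax` and the spacing are
configurable, and smaller `rmax` trades sensitivity to diffuse signal for
specificity.

## Null-model fitting

Under $H_0$ the mean model is ordinary least squares per vertex, computed
with one shared QR projector (identical to per-vertex fits, bit for bit).
The noise parameters minimize the covariance-regression objective

$$\sum_{i=1}^N \left\| \hat\epsilon_i \hat\epsilon_i' -
  \sigma^2 \Phi(\phi, D) - \tau^2 I \right\|_F^2 .$$

Because the objective is quadratic, it depends on the residuals only
through $\hat M = N^{-1} \sum_i \hat\epsilon_i \hat\epsilon_i'$, and the
implementation fits $\hat M$ directly (avoiding any $O(NV^2)$ memory). For
each candidate $\phi$ on a grid, the profile problem in
$(\sigma^2, \tau^2)$ is a 2×2 linear system in the Frobenius inner
products $\langle\Phi,\Phi\rangle$, $\langle\Phi,I\rangle = V$,
$\langle I,I\rangle = V$, solved in closed form; nonnegativity is enforced
by comparing the interior solution with the two active-set corners, and
$\tau^2$ is floored at $10^{-8}\,\overline{E^2}$ so the fitted covariance
stays positive definite. The grid default is 20 log-spaced values of
$\phi$ chosen so that the SACF at the median pairwise distance spans 0.95
down to 0.01 — from near-flat to essentially local autocorrelation on any
mesh scale. The returned $\phi$ attains the smallest objective on the grid
(asserted directly in the test suite by a grid sweep).

The spatial component of each image is then its best linear unbiased
predictor under the fitted null model,
$\hat b_i = \hat\sigma^2 \Phi(\hat\phi, D)\, \hat\Sigma^{-1} \hat\epsilon_i$
with $\hat\Sigma = \hat\sigma^2\Phi + \hat\tau^2 I$, computed per image
independently (the model makes residual images i.i.d., so joint pooling
would add nothing). The whitened residual $\hat\delta_i = \hat\epsilon_i -
\hat b_i$ feeds the score statistic. $\hat\Sigma^{-1}$ is applied by dense
Cholesky up to `exact_threshold = 2000` vertices, and above that by a
Vecchia-type nearest-neighbor Gaussian process factorization: vertices
ordered by their first spatial coordinate, each conditioning on its
`m = 50` nearest predecessors, giving a sparse approximate precision. The
suite verifies that the NNGP solve equals the dense solve exactly at
$m = V - 1$ and stays within a few percent at $m = 30$, $V = 200$. A
max-min ordering is a known alternative; coordinate ordering was chosen for
determinism and simplicity, and `m` is exposed.

## Score statistics and cluster enhancement

The per-vertex statistic is the variance-component score (SKAT-type)
quadratic form $U(v) = d(v)' K d(v)$, with $d(v)$ the whitened (full
pipeline) or plain OLS (non-spatial variants) residuals at vertex $v$. The
proportionality constant of the score test is irrelevant downstream —
standardization is scale invariant — so the unscaled form is used. Under
Gaussianity $U(v)$ is a mixture of $\chi^2_1$ variables whose weights are
the nonzero eigenvalues of the kernel conjugated by the residual-projection
factor; `null_mixture_weights()`, `rmixture_chisq()` and
`pmixture_chisq()` expose this law for validation (the test suite checks
the Monte-Carlo distribution of $U$ against it by a two-sample KS
distance), but inference never relies on it.

Neighborhood sums $S_r(v) = \sum_{u \in N_r(v)} U(u)$ are standardized per
(radius, vertex) cell by permutation moments and maximized, first over
radii per vertex, then globally. Ties in the per-vertex argmax radius take
the smallest radius; the global argmax vertex takes the lowest index (the
maximum value itself is tie-free in continuous data).

### Standardization moments: the pooled convention

Each cell's moments are the sample mean and sample standard deviation
(denominator $n - 1$) of an ensemble of statistics, and the same affine
transform is applied to the observed and to every permuted sum. Two
conventions are implemented:

* `moments = "pooled"` (default): the ensemble is the observed sum plus
  the $B$ permuted sums. The transform is then a symmetric function of
  $B + 1$ values that are exchangeable under $H_0$, so the observed and
  permuted global maxima remain *exactly* exchangeable and the test is
  calibrated at any $B$.
* `moments = "permuted"`: the ensemble is the $B$ permuted sums alone.
  The permuted standardized values then have mean 0 and standard deviation
  1 exactly — an attractive invariant — but the observed statistic is not
  part of the moment estimate, and at small $B$ the estimated scale's
  sampling error inflates the observed maximum relative to the permuted
  ones. The two conventions coincide as $B \to \infty$.

The default is pooled because calibration takes precedence over the
self-standardization invariant: in this package's own null simulations at
$B = 200$ the permuted-only convention yields an empirical FWER visibly
above the nominal 0.05 while the pooled convention does not (the
acceptance script reproduces this number). With the common practice of
$B \ge 5000$ permutations the choice is immaterial.

### Threshold convention

The FWER threshold is the $\lceil (1-\alpha)(B+1) \rceil$-th ascending
order statistic of the permuted maxima (capped at $B$). Treating the
observed maximum as the $(B+1)$-th exchangeable draw, rejecting when
$T > t_\alpha$ under this convention is identical to rejecting when the
standard permutation p-value $(1 + \#\{T^{(b)} \ge T\})/(B+1)$ is at most
$\alpha$, and spends at most $\alpha$ of the exchangeable ranks for every
$B$. The seemingly natural rank $\lceil (1-\alpha) B \rceil$ overshoots
the level by about $1/(B+1)$ — negligible at $B = 5000$, but a fifth of
the budget at $B = 200$ — so it was rejected. Both the global decision
($T > t_\alpha$) and the localization ($\{v: T(v) > t_\alpha\}$) use the
single threshold; the reported `p_global` uses the $(1 + \#)/(B+1)$ form,
which cannot be exactly zero.

### Permutation scheme

Shuffling images under $H_0$ is equivalent to shuffling the whitened
residual rows: the OLS projector is symmetric in images, and the
covariance fit depends on the residuals only through the
permutation-invariant $\hat M$, so no quantity needs refitting within
permutations. Each permutation is therefore one $N \times N$ by
$N \times V$ product plus sparse neighborhood sums. All randomness flows
from a single user-visible seed through a deterministic permutation
stream; identical configurations are bit-identical across runs. An
exchangeable kernel ($K = I$) makes every permuted statistic equal the
observed one; this degeneracy is detected and reported as an error rather
than silently producing zeros.

## Pipeline variants

`run_cleanv()` exposes the full method and its three ablations —
`no_spatial` (OLS residuals, enhancement kept), `no_enhance` (whitening
kept, radius 0 only), and `massive` (neither; the MEGHA-style
massive-univariate analysis). All share the identical permutation
machinery and, given the same seed, the same permutations, which makes the
definitional reduction `no_spatial` with radius 0 ≡ `massive` exact; the
suite asserts it to machine precision.

## The synthetic-data generator

`simulation_scenario()` + `simulate_dataset()` draw directly from the
generative model above on built-in meshes (planar unit-spacing grids and
icospheres). Defaults, chosen once as representative of surface-smoothed
task-fMRI contrast noise and the study designs the method targets:
`sigma2 = 1`, `tau2 = 1` (equal spatial and white noise);
`phi` set so the SACF equals 0.3 at the median pairwise geodesic distance
of the mesh in use (moderate, mesh-scale-free autocorrelation);
`theta2 = 1` on the signal region (effect size
$\theta^2/(\theta^2+\tau^2) = 0.5$); signal on a contiguous geodesic disc
covering ~10% of vertices (cluster enhancement is designed for contiguous
signal); 20 test–retest pairs ($N = 40$) or 60 twin pairs ($N = 120$) with
60% MZ pairs. The null mode mirrors pseudo-pair designs: the analysis is
handed a $K$ that labels images as pairs while the generating truth has no
between-image dependence, and `prop_true` interpolates between that null
and a fully paired design.

What the generator deliberately does not emulate: real task-fMRI noise is
nonstationary, anisotropic, and non-Gaussian, with vertex-varying
$\tau^2(v)$ and signal regions inherited from actual activation
topography. Passing calibration and power tests under this generator
therefore demonstrates correctness of the machinery under its own model,
not robustness to those violations — although FWER control itself rests
only on image exchangeability, which pseudo-pair nulls of real data would
also satisfy. Resampling-based simulation from user-supplied images is out
of scope.

## Numerical choices and degenerate inputs

* PSD validation of relatedness matrices tolerates eigenvalues down to
  $-10^{-8}\,\|K\|_2$; custom matrices are symmetrized as $(K + K')/2$
  first.
* The test–retest kernel keeps its unit diagonal. Replacing $K$ by
  $K - I$ shifts every $U(v)$ by $\sum_i d_i(v)^2$, which row permutations
  preserve, so all standardized statistics are unchanged — asserted as a
  unit test, making the diagonal convention immaterial.
* The SACF Cholesky in the simulator falls back to a $10^{-8}$ diagonal
  jitter if the exponential kernel on graph distances (which are not
  exactly Euclidean) is numerically semidefinite.
* Rank-deficient covariate matrices, empty masks, non-square or indefinite
  kernels, out-of-range face indices, negative radii, and zero-variance
  standardization cells are all rejected with specific errors naming the
  offending object.
* Face files default to 0-based indexing on disk (1-based in memory, the R
  convention); 1-based files are accepted via `index_base = 1`.

## Problem sizes in the shipped checks

The test suite and acceptance script are sized for a single CPU: the
calibration study uses a 17×17 grid (289 vertices), 20 pseudo pairs,
radii 0–10 mm, $B = 200$, and 500 replicates per variant; the power
monotonicity check uses a 10×10 grid with 200 replicates per effect-size
level; oracle comparisons (Floyd–Warshall distances, double-loop quadratic
forms, dense BLUP solves) run on meshes of at most 50 vertices. These
sizes are the package's choices for routine verification; the method
itself has been exercised at $V$ in the thousands, where the NNGP path
takes over.

## Known limitations

* Only the exponential SACF is implemented; Matérn or nonstationary
  covariances would require replacing one matrix-valued function but are
  untested.
* The effect-size estimator is a descriptive method-of-moments companion;
  it is biased upward near zero (the ratio is clipped to $[0, 1]$) and is
  not part of the test.
* Geodesics are graph-based; on very coarse or highly irregular meshes the
  neighborhood shapes can deviate from true geodesic discs.
* Inference localizes vertices exceeding one global threshold; it does not
  produce vertex-wise adjusted p-value maps or model $\theta^2(v)$
  spatially.
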