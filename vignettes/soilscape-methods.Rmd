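---
title: "Methods: geostatistics and variance partitioning for landscape-scale soil microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geostatistics and variance partitioning for landscape-scale soil microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, the
numerical conventions adopted where the methodology literature leaves a
choice open, and the known limitations.  It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Geostatistical model

Every mapped variable is treated as one realization of a stationary,
isotropic Gaussian random field *after* a rank transformation.  The
chain is:

1. **Normal-scores transform** — values are mapped to
   `qnorm((r - 0.5)/n)` where `r` is the (average, for ties) rank.  Hazen
   plotting positions are the common geostatistical default; tied values
   share one score.  The transform is stored as an empirical score–value
   graph so it can be inverted.
2. **Matérn semivariogram**
   `γ(h) = c0 + c1 [1 − (2^{1−v}/Γ(v)) (h/a)^v K_v(h/a)]` with nugget
   `c0 ≥ 0` (micro-scale + measurement variance), partial sill `c1 ≥ 0`
   (spatially structured variance), range parameter `a > 0` in metres,
   and smoothness `v > 0`.  The family nests the exponential model
   (`v = 0.5`) and approaches the Gaussian model as `v` grows, so one
   family covers rough and smooth fields; soil properties typically fit
   with low `v`, which is why `v` is estimated freely (bounds
   `[0.05, 5]`) in maximum-likelihood fits unless fixed by the caller.
3. **Fitting** — `fit_variogram()` offers weighted nonlinear least
   squares on the method-of-moments empirical variogram (weights `N(h)`,
   the bin pair counts — the simplest defensible choice; Cressie weights
   would be a one-line change) and maximum likelihood under a constant
   unknown mean, with the total variance profiled out analytically and
   the nugget fraction logit-parameterised.  Both use multiple seeded
   starts; an optimum on a parameter bound is flagged in the returned
   model rather than silently accepted.
4. **Ordinary kriging** — solved with the full neighbourhood (the site
   counts this package targets are a few hundred, so no search
   neighbourhood is needed and the unbiasedness constraint is exact).
   Predictions are back-transformed through the empirical graph by
   piecewise-linear interpolation, **clamped** at the observed extremes:
   no tail model is invented, so kriged maps never extrapolate beyond the
   data range.  Kriging variances are reported in rank space, where the
   Gaussian assumption actually holds.

### Model validation (SSPE)

Leave-one-out cross-validation gives standardized squared prediction
errors `θ(x_i) = (z_i − ẑ_{−i})² / σ²_{k,−i}`.  Under a correct model the
`θ` are χ²(1): mean 1, median 0.455.  Because mean and median of `θ` have
awkward finite-sample distributions, `sspe_diagnostics()` simulates the
fitted model `M` times (default 1000) at the data locations —
unconditionally and without refitting, the common form of the procedure —
and reports empirical 2.5/97.5% limits plus a within/outside verdict.
SSPE is computed in rank space; whether the original study did the same
is not documented, so the report labels the space explicitly.

The leave-one-out weights depend only on geometry and model, never on the
data.  `loo_cross_validate()` therefore factors the kriging system once
per call, and the simulation loop inside `sspe_diagnostics()` (and the
acceptance script) reuses one system for all simulated fields; the test
suite verifies the reused system against per-site re-kriging.

### Effective range

Reported as the smallest `h` where `γ(h) − c0 ≥ 0.95 c1` (root search).
The 95% convention is standard; for `v = 0.5` it equals `2.9957·a`.  It is
undefined for pure-nugget models and raised as an error rather than
returned as 0 or infinity.

## 2. Community structure

* **Rarefaction** to a common depth (default 10,800 reads, the depth the
  sampling design this package emulates was sequenced to) by exact
  sampling without replacement; sites below depth are dropped with a
  warning, never padded.
* **Weighted UniFrac**, normalized:
  `d(A,B) = Σ_e b_e |p_A(e) − p_B(e)| / Σ_e b_e (p_A(e) + p_B(e))`
  over tree branches.  Normalization bounds the distance in [0, 1], which
  site-to-site comparisons need; the raw branch sum is available via
  `normalized = FALSE`.
* **NMDS** delegates the stress minimisation to `vegan::monoMDS`
  (global model, weak ties by default — the tie treatment is an argument
  because the original choice is rarely reported), initialized from
  classical scaling plus `restarts` random configurations; the best
  stress wins.  Stress never increases with `k` (tested).
* **Vector fitting** regresses each variable on the ordination scores.
  `R²` is the squared multiple correlation, the direction is the
  unit-norm coefficient vector, and `p` uses the add-one permutation rule
  `p = (1 + #{R²_perm ≥ R²}) / (1 + n_perm)`.

### Why retention tests use `p ≤ α`, not `p < α`

With 999 permutations the smallest attainable add-one p-value is exactly
1/1000.  A printed threshold of "P < 0.001" at 999 permutations can only
ever be met by that smallest value, so the operative rule is `p ≤ α`.  A
strict inequality would make every permutation test at `α = 1/(n_perm+1)`
unpassable by construction.

## 3. Spatial predictors (PCNM)

Classic PCNM: truncate the inter-site distance matrix at a threshold
(distances beyond it replaced by 4× the threshold), double-centre as in
PCoA, eigendecompose, keep eigenvectors with eigenvalue
`> 1e-8 × λ_max`.  The auto-threshold is the longest minimum-spanning-tree
edge — the standard rule that guarantees the truncated graph stays
connected.  Eigenvectors are unit-norm, centred, and sign-fixed (first
nonzero loading positive) so results are bit-reproducible.  All
positive-eigenvalue vectors are retained; Moran's-I sub-selection is out
of scope.  The number of PCNMs is data-dependent (a 278-site grid yields
about 190) and deliberately not pinned to any particular survey's count.

## 4. Variance partitioning

* **Pruning** (`prepare_blocks`): two passes.  Pairwise: while any |r|
  exceeds the threshold (default 0.9), drop the member of the worst pair
  with the larger mean absolute correlation to everything else — this is
  what removes total nitrogen (r = 0.92 with organic carbon) from the
  default landscape.  Exact dependence: QR rank deficiency detects
  compositional closure (clay + silt + sand = 100) and drops, among the
  dependent set, the column with the largest mean |r| — silt, in the
  default landscape.
* **Forward selection** (`forward_select`): a candidate enters only if
  its permutation p ≤ α *and* AIC = `n log(RSS/n) + 2k` decreases
  (k counts predictors plus intercept).  Spatial descriptors are selected
  by passing the residuals of the environmental model as the response, so
  the spatial block only absorbs structure the environment cannot.
* **Fractions**: adjusted R² by Ezekiel's formula, folded as
  soil-only = `R²a(S+M) − R²a(M)`, management-only = `R²a(S+M) − R²a(S)`,
  shared(S∩M) = `R²a(S) + R²a(M) − R²a(S+M)`, space-only =
  `R²a(S+M+P) − R²a(S+M)`, residual = `1 − R²a(S+M+P)`.  These five sum
  to 1 identically; negative adjusted fractions are reported, never
  clipped.  Three-way overlaps with space are folded into the space
  increment because the residual-based spatial selection makes the space
  block approximately orthogonal to the others by construction.
* **db-RDA** (`partition_community`): the distance matrix is embedded by
  PCoA; if negative eigenvalues exceed `1e-8 λ_max` (weighted UniFrac is
  not guaranteed Euclidean) the additive Lingoes correction is applied.
  The coordinate matrix is then analysed by redundancy analysis; on
  Euclidean distances this reproduces direct RDA to 1e-8 (tested against
  vegan).  Block significance uses reduced-model residual permutation
  with an F-like statistic.

### The selection-aware permutation null

At each forward-selection step the statistic actually computed is *the
best adjusted-R² gain over all remaining candidates*.  The permutation
p-value therefore compares that maximum to the distribution of the
*maximum* over candidates in each permutation (a family-wise null), not
to the single chosen candidate's own null.  With a per-candidate null,
picking the best of `m` candidates and then testing it inflates the
per-step type-I rate roughly `m`-fold (≈1% for 10 candidates at
α = 0.001), and pure-noise selection could not be calibrated at α.  With
the family-wise null the pure-noise false-selection rate is α per step,
which the acceptance suite verifies (≥ 99% empty selections over 200
noise replicates).

## 5. The synthetic landscape: what it emulates, what it does not

The generator reproduces the *statistical design* the analysis assumes:

* a 215 m square lattice of 248 sites plus 30 infill sites placed
  uniformly inside lattice cells (hence always < 215 m from a grid site);
* Matérn-correlated soil fields whose defaults give effective ranges of
  roughly 600–900 m, means/SDs typical of a silty-clay agricultural
  landscape (pH 7.7, organic carbon 25 g/kg, …), an exact compositional
  texture triple, and a 0.92 organic-carbon–total-nitrogen correlation;
* six contiguous land-management clusters grown by seeded Voronoi
  accretion to exact counts (44, 7, 22, 57, 33, with the largest cluster
  padded from 104 to 115 because the six published counts sum to 267, not
  278; counts are free parameters and are rescaled proportionally for
  smaller test landscapes);
* compositional taxon tables from a logistic-normal-multinomial forward
  model: softmax of baseline + per-SD soil coefficients + cluster offsets
  + a Matérn residual + iid overdispersion, drawn multinomially at a
  10,800-read library.

Cross-correlations are imposed by Cholesky mixing of *empirically
orthonormalized* unit fields, so realized site-sample correlations hit
their targets to numerical precision rather than only in expectation.
The cost is that a mixed field is a linear combination of fields with
(possibly) different variograms; when partners share spatial structure —
as the correlated defaults do — the marginal variogram is preserved
exactly.

What the generator does **not** emulate: real pedology or hydrology
(rivers, soil-type maps), anisotropy, management-conditional soil shifts
(off by default so the correlation contract stays exact; available via
`cluster_effects`), taxon–taxon interactions, sequencing error or OTU
clustering artefacts, and non-multinomial count noise beyond the logit
overdispersion term.  A green closed-loop test therefore establishes that
the *estimators recover the stated generating structure* — not that real
landscapes satisfy that structure.

## 6. Numerical conventions and degenerate inputs

* Matérn correlation: `ρ(h) = 1` for `h/a < 1e-10`; Bessel underflow at
  large lags maps to `ρ = 0`; results clamped to [0, 1].
* Covariance factorisations use plain Cholesky; a failure is reported as
  a non-positive-definite error naming the offending parameters
  (coincident sites with zero nugget being the canonical trigger).
* Empirical variogram: empty bins carry `NA`, never 0; pairs at exactly
  zero distance are excluded.
* Constant variables: an error for the normal-scores transform (no rank
  information), a warning-and-skip for vector fitting and PCA, pruning
  for predictor blocks.
* Leave-one-out variances below 1e-12 flag the site and yield `NA` θ
  rather than dividing by ~0.
* Zeros in log-transformed relative abundances are replaced by half the
  taxon's smallest positive value — a documented convention; the log has
  to do *something* with rarefied zeros.
* Seeds: a single master seed; every stochastic stage derives a named
  child seed (`derive_seed`), all below 2³¹, so partial re-runs reproduce
  exactly.  Pipeline configs serialize to JSON (no YAML parser in the
  supported dependency set).

## 7. Known limitations

* No co-kriging, universal kriging, anisotropy, or Bayesian variogram
  inference; coordinates are planar metres with Euclidean distances.
* ML fitting is O(n³) per likelihood evaluation; practical to ~1000
  sites, not beyond.
* The WLS and ML routes agree to <1% only in the zero-residual limit
  (WLS on exact model curves); on finite noisy fields they differ by
  sampling variability, which is inherent, not a defect.
* Weighted UniFrac is quadratic in sites with a per-pair branch sum;
  fine for hundreds of sites, slow for tens of thousands.
* The shared fraction is reported only for soil∩management; with the
  residual-based spatial selection the unreported three-way overlaps are
  near zero by construction, but they are folded, not estimated.
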