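# soilscape

Landscape-scale spatial analysis of soil bacterial and archaeal
communities: geostatistical mapping of community structure and taxon
abundances, phylogenetic ordination, and variance partitioning of community
variation among soil, land-management and spatial predictors — together
with a synthetic landscape generator so the whole pipeline can be
developed, calibrated and tested without field data.

## Who this is for

Microbial ecologists and soil scientists working with site-by-taxon tables
from landscape surveys (hundreds of sites a few hundred metres apart) who
want to (i) map community metrics and taxon abundances across the
landscape with honest uncertainty, and (ii) quantify how much of the
variation is attributable to soil physicochemistry, land management, and
pure spatial structure.

## The statistics at the core

**Normal-scores ordinary kriging with Matérn variograms.** Soil and
community variables rarely look Gaussian, so each variable is first mapped
to standard-normal quantiles of its Hazen plotting positions
((r − 0.5)/n).  Spatial dependence is modelled by the Matérn semivariogram

γ(h) = c₀ + c₁ [1 − (2^{1−v}/Γ(v)) (h/a)^v K_v(h/a)],

with nugget c₀, partial sill c₁, range parameter a (m) and smoothness v
(v = 0.5 is the exponential model).  Models are fitted either by weighted
least squares on the method-of-moments empirical variogram or by maximum
likelihood directly on the (rank-transformed) data.  Ordinary kriging is
performed in rank space and predictions are back-transformed; kriging
variances stay in rank space, where the Gaussian assumption holds.

**SSPE validation.** A fitted model is checked by leave-one-out
cross-validation: θ(xᵢ) = (z(xᵢ) − Ẑ₋ᵢ(xᵢ))² / σ²ₖ,₋ᵢ(xᵢ) is χ²(1) under a
valid model, with mean 1 and median 0.455.  Simulating the fitted model at
the data sites gives empirical 95% limits for both statistics.

**Community structure.** Counts are rarefied to a common depth (default
10,800), distances are normalized weighted UniFrac over a phylogeny, the
ordination is NMDS (Kruskal stress-1, PCoA start + random restarts), and
environmental/taxon vectors are fitted by regression on the ordination
scores with add-one permutation p-values (retention: R² ≥ 0.20, p ≤ 0.001
at 999 permutations).

**Variance partitioning.** Predictors form three blocks — soil
(standardized, collinearity-pruned), land management (dummy-coded
clusters) and space (PCNM eigenvectors of the truncated inter-site
distance matrix).  Variables enter by forward selection that must both
pass a permutation test (p ≤ α, family-wise over candidates) and decrease
AIC = n·log(RSS/n) + 2k; spatial descriptors are selected from the
residuals of the environmental model.  Adjusted-R² (Ezekiel) fractions are
reported as soil-only, management-only, shared(soil∩management),
space-only and residual, for single taxa (partial regression) and for the
community distance matrix (db-RDA on principal coordinates with Lingoes
correction, reduced-model residual permutation).

**Synthetic landscapes.** `generate_sampling_design()` reproduces a
215 m square-grid survey (248 grid + 30 infill = 278 sites);
`attach_soil_and_management()` realizes Matérn-correlated soil fields with
exact target cross-correlations (e.g. r = 0.92 between organic carbon and
total nitrogen) and six contiguous land-management clusters with exact
counts; `simulate_community()` draws multinomial taxon counts from a
logistic-normal (softmax) forward model with per-taxon soil responses,
cluster offsets and spatially structured residuals.

## Worked example

```r
library(soilscape)

design <- generate_sampling_design(spacing = 215, n_grid = 248,
                                   n_infill = 30, seed = 1)
sites  <- attach_soil_and_management(design, seed = 1)

## map soil pH: normal scores -> ML Matérn fit -> SSPE validation
ns  <- normal_scores_transform(sites$pH)
xy  <- cbind(sites$x, sites$y)
fit <- fit_variogram(method = "ml", site_xy = xy, values = ns$scores,
                     v = NA, seed = 1)
fit
#> Matern variogram model (ml): c0 = 0.3241, c1 = 0.6623, a = 147.2 m, v = 1.16
#>   objective: 360.216
effective_range(fit)   # 626 m: mid-range spatial patches
sspe_diagnostics(xy, ns$scores, fit, M = 1000, seed = 1)
#> SSPE leave-one-out diagnostics (n = 278, 1000 simulations)
#>   mean   1.007  [95% limits 0.831, 1.195]  within  (reference 1)
#>   median 0.405  [95% limits 0.348, 0.600]  within  (reference 0.455)
#>   computed in rank (normal scores) space
```

Both SSPE statistics fall inside their simulated 95% limits, so the fitted
model is a valid description of the spatial variation and the kriged map
(`ordinary_kriging(xy, ns$scores, fit, grid, ns_map = ns$map)`) can be
trusted.

```r
## community structure: rarefy -> weighted UniFrac -> NMDS -> vectors
comm <- simulate_community(sites, default_community_spec(), seed = 1)
rare <- rarefy_counts(comm, depth = 10800, seed = 1)
tree <- simulate_taxa_tree(comm$taxon, seed = 1)
D    <- weighted_unifrac(rare, tree)
ord  <- nmds(D, k = 2, seed = 1)
ord
#> NMDS ordination: 278 sites x 2 axes
#>   stress: 0.1048 (best of 21 starts)
fit_vectors(ord, sites[, c("pH", "organic_carbon", "caco3", "clay")],
            n_perm = 999, seed = 1)
#>         variable   NMDS1  NMDS2      r2     p retained
#> 1             pH  0.5959 -0.803 0.63732 0.001     TRUE
#> 2 organic_carbon -0.0461  0.999 0.22125 0.001     TRUE
#> 3          caco3  0.1175  0.993 0.00179 0.805    FALSE
#> 4           clay -0.6113 -0.791 0.10562 0.001    FALSE
```

A stress of 0.10 means two axes describe the community variation well; pH
dominates axis 1 and organic carbon axis 2 (clay is significant but below
the R² ≥ 0.20 retention threshold — exactly the filtering the report
applies).

```r
## variance partitioning of one taxon
basis  <- build_pcnm(xy)                       # 187 spatial eigenvectors
blocks <- prepare_blocks(sites, pcnm = basis)
blocks
#> Predictor blocks: soil 5, management 5, space 187
#>   pruned: total_nitrogen (|r| = 0.920 with organic_carbon); silt (linearly dependent)
p <- community_matrix(aggregate_taxonomy(rare,
       "phylum_with_proteobacteria_classes"), proportions = TRUE)
y <- log_transform_abundance(p["Alphaproteobacteria", ])
partition_abundance(y, blocks, n_perm = 999, seed = 1)
#> Variance partition (abundance):
#>   soil         0.580  (p = 0.001)
#>   management   0.053  (p = 0.348)
#>   shared       0.112
#>   space        0.107  (p = 0.001)
#>   residual     0.147
```

The generator gave Alphaproteobacteria a pH response and a weak
management gradient, and the partition recovers that: soil explains 58% of
the variance (p = 0.001), management adds little on its own, and a modest
spatial fraction remains.

## Full pipeline and CLI

```r
cfg <- pipeline_config(seed = 1)
run_pipeline(cfg, "run1")     # sites.csv, community.tsv, unifrac.tsv,
                              # nmds_scores.csv, surfaces, pcnm.csv,
                              # taxon_partitions.csv, summary.json, ...
```

or from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "soilscape.R", package = "soilscape"))')" \
    run --config config.json --seed 1 --out run1
```

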