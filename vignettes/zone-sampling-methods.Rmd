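---
title: "Terrain-based zone delineation and soil sampling design with somzones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terrain-based zone delineation and soil sampling design with somzones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Soil microbial biomass and activity vary strongly within single
agricultural fields, largely following terrain-driven moisture and
carbon gradients.  Exhaustive pre-sampling to map that variation is
rarely affordable, so a practical sampling design has to lean on
covariates that are cheap to observe everywhere: elevation and its
derivatives, and apparent electrical conductivity (EMI) sensed from a
towed sled.  `somzones` implements a complete workflow of this kind:

1. derive slope, aspect and plan curvature from a 10 m gridded DEM;
2. interpolate horizontal (H-H) and vertical (V-V) coil EMI transects
   to the same grid by inverse distance weighting;
3. z-score the six attributes into an `n x 6` feature matrix;
4. train a self-organizing map (SOM) on the feature vectors and
   partition its codebook with K-means into `k` zones;
5. select, per zone, the field location closest to the zone centroid
   (the "best matching unit", BMU) plus spatially spread additional
   sites;
6. compute microbial indicators from raw assays and test how the
   indicators differ across zones and how well each BMU represents its
   zone.

```{r, eval = FALSE}
library(somzones)
sim <- simulate_field(synthetic_field_config(), seed = 1)
pl <- run_zone_pipeline(sim$dem, sim$emi_points$hh, sim$emi_points$vv,
                        k = 3, n_additional = 11, seed = 1)
pl$design          # 36 sites: 3 zones x (1 BMU + 11 additional)
```

## The self-organizing map

Each lattice node `i` holds a prototype vector `m_i` in the normalized
feature space.  Presenting an input `x`, the winning node `c` minimizes
the Euclidean distance `||x - m_i||` (ties broken toward the lowest
node index, for determinism).  Sequential training then moves every
node toward the input,

    m_i(t+1) = m_i(t) + h_ci(t) [x(t) - m_i(t)],

with a Gaussian neighborhood
`h_ci(t) = alpha(t) exp(-d_lattice(c,i)^2 / (2 sigma(t)^2))`.  Because
`h_ci` is in `(0, alpha]` and `alpha < 1`, every update is a convex
combination, so trained prototypes stay inside the per-coordinate hull
of the initial codebook and the presented inputs — a property the test
suite checks.

Choices the method leaves open, and the defaults adopted here (all
arguments of `som_codebook()` / `som_schedule()`):

* **Map size**: `N = ceil(5 sqrt(n))` nodes, rows:columns matched to
  the square root of the ratio of the two leading covariance
  eigenvalues.  This is the long-standing SOM-toolbox sizing heuristic;
  for the default 7050-location field it gives a hexagonal lattice of
  about 28 x 15 nodes (the exact split follows the data).
* **Topology**: hexagonal, so interior nodes have six equidistant
  neighbours; `rectangular` is available.
* **Initialization**: "linear" — nodes laid on the plane of the first
  two principal components, spanning ±2 SD — which is deterministic
  given the data.  A seeded random initialization (sampling input rows)
  is provided as well.
* **Schedule**: two phases decaying linearly; rough
  (`sigma: max(rows, cols)/4 -> 1`, `alpha: 0.5 -> 0.05`, `10 n` steps)
  then fine (`sigma: 1 -> 0.1`, `alpha: 0.05 -> 0.01`, `40 n` steps).
  Updates are truncated beyond 3 `sigma` of lattice distance, where the
  Gaussian weight is below 1.2 % of its peak.
* **RNG**: a single seed drives input sampling (and random
  initialization when used); with a fixed seed, training is
  bit-reproducible.

Training quality is summarized by the quantization error (mean winner
distance), and the trained map by the U-matrix: per-edge prototype
distances on the lattice, whose ridges mark candidate zone boundaries.

## Zone delineation and site selection

K-means (Lloyd iteration, best of 10 seeded restarts by within-cluster
sum of squares; empty clusters re-seeded from the farthest point)
partitions the *node* prototypes; each field location inherits the
cluster of its winning node.  The cluster count `k` is deliberately a
user decision — it is normally read off the U-matrix — with
`davies_bouldin_scan()` available as numerical guidance only.  Cluster
ids are renumbered by descending membership for stable reporting; any
"cluster 1 = potholes" interpretation is left to the analyst.

Zone centroids for site selection are recomputed as means of the member
*locations* (not node prototypes), and the BMU site of a zone is the
member location closest to that centroid.  Additional sites spread each
zone's sample geographically by greedy farthest-point selection seeded
at the BMU: repeatedly add the member maximizing its minimum distance
to the already-selected sites, ties toward the lowest row index.  The
greedy rule is deterministic and includes the BMU by construction; it
is not guaranteed to attain the exhaustively optimal max-min
dispersion (it carries the classic factor-2 guarantee, which the tests
verify on small instances).  A zone with fewer than `1 + n_additional`
members contributes all of them and the shortfall is reported.

## Microbial indicators

`microbial_biomass()` converts chloroform-fumigation differences to
biomass pools with calibration factors 0.45 (C) and 0.54 (N); negative
extraction differences are floored at zero and flagged, since a biomass
pool cannot be negative.  `c_mineralization_rate()` fits an ordinary
least-squares slope to cumulative CO2 over the incubation days
(readings are post-venting increments, so their running sum is the
cumulative production); using all four sampling days rather than an
endpoint difference makes the rate robust to a single noisy reading.
`n_mineralization()` is the signed 28-day change in extractable
inorganic N (negative = net immobilization, passed through), and
`specific_rate()` normalizes a rate per unit biomass C, undefined (and
flagged) when MBC is not positive.  Extractable organic C is identified
with the non-fumigated extract's dissolved organic C.

## Statistics

* `correlation_table()`: Pearson r for every landscape attribute x
  indicator pair; reports round to 2 decimals.  Aspect enters linearly
  in degrees — a documented limitation near the 0/360 wrap, accepted
  because the feature matrix carries aspect the same way.
* `anova_by_cluster()`: one-way ANOVA with all-pairs Tukey HSD at
  `alpha = 0.05` summarized as compact letters (clusters sharing a
  letter are not distinguishable).  No correction is applied across
  indicators.  Letters come from maximal non-significant cliques of the
  pairwise p-value matrix, fine for the small `k` used here.
* `bmu_representativeness()`: a two-sided one-sample t-test of the
  non-BMU members against the BMU's single observation.  A two-sample
  test is impossible with one BMU observation, so this one-sample form
  is the testable reading of "does the BMU estimate the zone mean";
  results depend on that choice and it is therefore stated prominently.
* `cluster_ratio_summary()`: ratios of zone means, the effect-size
  language used to describe zone contrasts (for example "zone 1 mean
  1.6 x the others").

## The synthetic field generator

`synthetic_field_config()` encodes the study conditions the package is
validated under — a low-relief till field of 75 x 94 cells at 10 m
(7050 locations), 6 m total relief, with three planted zones:

* **zone 1**: closed depressions ("potholes") and toe slopes.  Pits are
  shallow, sediment-filled bowls (0.3-0.5 m deep, 30-45 m radius);
  deep steep pits would give this zone every compass aspect and both
  curvature signs, which no till-plain field shows.
* **zone 2**: the south-facing flank of a NW-SE ridge, 1.4 x steeper
  than zone 3.
* **zone 3**: the northeast-facing flank.

EMI readings are sampled along sled-like transects (20 m pass spacing,
5 m along track) as
`base + coef (elev - mean elev) + zone offset + noise`, with negative
coefficients (wet, fine-textured lows conduct more) and zone offsets
placing the depressions ~15 mS/m above the uplands.  The resulting
summaries sit near the targets the configuration states (H-H mean 47,
SD ~14; V-V mean 32.6, SD ~11).  Indicators are drawn per site from
`Normal(zone mean, cv * zone mean)`; zone-1 means carry the configured
multipliers (MBC x1.6, MBN x1.75, %TN x1.8, %TC x1.6, EOC x1.3,
specific rates inverted), and `null_effects = TRUE` switches every
multiplier to 1 for type-I-error calibration.  Coefficients of
variation (15-30 % for pools and rates) are typical of field-scale
microbial assays and give the 12-sites-per-zone design high power for
the configured contrasts.

What the generator does *not* emulate: spatial autocorrelation of the
indicator noise, seasonal dynamics, physically based EMI response, or
measurement error in the DEM beyond smoothed microtopography.  Passing
the recovery tests therefore shows the pipeline recovers structure *of
the kind the generator plants*, not that any real field will divide
into three zones.

## Numerical choices

* Terrain derivatives use the 3 x 3 Zevenbergen-Thorne quadratic fit;
  grid edges fall back to one-sided first differences (implemented by
  linear extrapolation of the missing neighbour, which also zeroes the
  edge second difference); any cell with a nodata neighbour is nodata.
  Plan curvature is signed positive-convergent by default
  (`convergent_positive = FALSE` flips it); cells flatter than 1e-8 %
  slope have no aspect (nodata) and zero plan curvature.
* IDW defaults to power 2 over the 12 nearest observations — the
  conventional choice when the survey does not state its parameters —
  and a cell within 1e-9 m of an observation takes its value exactly.
* Feature normalization requires non-constant columns and errors
  naming any constant column rather than silently dividing by zero.
* All tie-breaks (winner search, BMU site, farthest-point) go to the
  lowest index; every stochastic step takes an explicit seed, and
  re-running with the same inputs and seeds reproduces outputs
  bit-for-bit.

## Problem sizes used in validation

The test suite validates operations against brute-force oracles on
hundreds of small random instances, and the end-to-end recovery claims
on the default 7050-location field: zone recovery is scored as median
best-permutation accuracy over 20 generated fields, effect-size
recovery and ANOVA power over 50 generated 36-site sample tables, and
the ANOVA's type-I error over 1000 null tables.  The same quantities
are recomputed from scratch by `scripts/acceptance.R`.

## Known limitations

* Aspect is treated as a linear variable throughout (matrix, SOM,
  correlations); fields whose zones straddle due north will see
  inflated aspect variance.
* K-means runs on the codebook's node vectors, so node-level SSE
  drives the partition; zones that are wide in feature space can be
  split before narrowly separated zones are distinguished.  The
  U-matrix should always be inspected rather than trusting a fixed
  `k`.
* Site-for-site reproduction of any particular historical design is
  out of scope: the additional-site rule is one defensible reading of
  "spatially distributed", not a reconstruction.
* Elevation gridding from raw GPS tracks is not included; the pipeline
  starts from a gridded DEM.
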