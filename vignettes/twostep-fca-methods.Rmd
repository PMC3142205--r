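---
title: "Measuring spatial accessibility to clinics with the two-step floating catchment area method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatial accessibility to clinics with the two-step floating catchment area method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepfca)
```

## The problem and the model

Potential spatial accessibility asks how much clinical supply a resident
could plausibly reach, given where clinics are, how large they are, and
where people live. The two-step floating catchment area (2SFCA) method
answers this with two sweeps over a distance matrix between demand zones
(small census units with populations in the hundreds) and supply sites
(clinics), using a single catchment radius `d0`:

1. **Supply step.** Each clinic `j` receives a supply-to-demand ratio
   over the population inside its catchment, scaled per 1,000 persons:

   `R_j = 1000 * S_j / sum(D_k : d_kj <= d0)`

2. **Demand step.** Each zone `i` sums the ratios of all clinics inside
   its own catchment:

   `A_i = sum(R_j : d_ij <= d0)`

`A_i` is therefore in supply units per 1,000 persons. The *conventional*
variant counts clinics (`S_j`, default 1 per clinic) against total
population `D_k`. The *optimized* variant recognises that clinics differ
in size and populations differ in how much care they use: the supply
weight becomes the physician count `P_j`, and the demand weight becomes
the *potential users* `W_k = sum_x c_x * P_x` — the zone's age-group
populations `P_x` weighted by age-specific past-year clinic-utilization
proportions `c_x` (0 to 1). The packaged schedules
(`load_default_schedules()`) carry the published Montreal, Quebec and
Canada proportions over nine age bins (0--14, 15--19, then ten-year bins
to 79, and 80+); Montreal is the default. With the Montreal schedule
`W_k/D_k` always lies between .606 and .895, the extreme coefficients.

Both variants are *binary-catchment* 2SFCA: a clinic either is or is not
reachable. No distance-decay weight is applied within the catchment —
the enhanced/gravity variants are deliberately out of scope.

### Missingness semantics

Two kinds of emptiness are kept distinct and never conflated with zero:

* a clinic whose catchment holds no demand has an **undefined ratio**
  (NA, with a warning); it contributes nothing in step 2;
* a zone with no clinic within `d0` has a **missing score** (NA), not
  `A = 0`. Summaries (`summarize_scores()`) count defined scores only,
  which is why the reported N grows with the threshold.

When every catchment is non-empty and every zone has access, the method
conserves supply exactly: `sum(D_i * A_i) / 1000 = sum(S_j)` (and the
`W`/`P` analogue). The test suite asserts this to 1e-9 relative error,
and checks the vectorized engine against a literal one-site-at-a-time
double loop on dozens of random instances.

## Distances and catchments

Catchments use a closed threshold (`d <= d0`): "within" is read
inclusively, so a zone exactly at the radius belongs to the catchment.
The default thresholds follow common walking/short-trip bands: 500,
1000, 2000 and 3000 m.

Two travel metrics are provided. Euclidean distance is the fast
baseline. Street-network distance (`shortest_path_distance_matrix()`)
snaps each point to its single nearest network node (ties broken by
lowest node id) and runs Dijkstra on the edge lengths; unreachable pairs
get `Inf` and fall outside every catchment. The point-to-node access hop
is *not* added by default — this keeps small worked examples exact — and
can be enabled with `add_access_distance = TRUE`. All coordinates must
be projected planar meters; lon/lat input is rejected rather than
silently misinterpreted, because every distance in the method is metric.

Zone centroids are accepted as supplied. Whether a centroid is geometric
or population-weighted is a data-producer's choice that materially
affects aggregation error; when only polygons are given the package
computes area centroids, and documents that choice rather than hiding
it.

## Comparing the two variants

Because the two variants are on different scales (clinics vs physicians
per 1,000), per-zone comparison first rescales each score vector to
0--100 over its range:

`rescaled = 100 * (A - min A) / (max A - min A)`

The difference score `D = rescaled_conventional - rescaled_optimized` is
computed only on zones where **both** methods are defined (the rescaling
is done within that intersection, since both values are needed anyway).
Negative `D` means the conventional method under-estimates accessibility
relative to the optimized one. A constant score vector has no defined
rescaling and errors out rather than returning 0/0.

Three statistics summarise the comparison at each threshold:

* **Spearman's rank correlation** between the raw scores (Pearson on
  average ranks; two-sided p from the t approximation on n − 2 df);
* a **t-test** on `D`. The default is a one-sample test of
  `mean(D) = 0`, because a single mean difference with one p-value per
  threshold is what per-zone difference scores naturally support; a
  Welch two-sample mode on the two rescaled vectors is also provided for
  users who prefer treating the methods as independent samples. The two
  agree in sign but not generally in p-value; the package does not
  assert either as canonical.
* the **difference percentile table** (mean, p, percentiles
  5/10/25/50/75/90/95).

All percentiles in the package use linear interpolation between order
statistics (`quantile(type = 7)`), the most common convention; no
multiple-testing correction is applied across thresholds.

## Spatial statistics

`morans_i()` computes the classic global Moran's I with **raw** weights
(no row standardization, available separately via `row_standardize()`),
expectation −1/(n−1), and a two-sided p-value from the z-score. The
default variance is the normality-assumption formula, matching the
plain-z-score reporting convention; the randomization variance is an
option (and is what the independent cross-check against `ape::Moran.I`
uses, since that implementation row-standardizes and permutes). Queen
contiguity links zones sharing any boundary point — edge *or* single
vertex — detected geometrically with an exact-coordinate fast path and a
`tolerance` parameter for digitized data. The inverse-distance-squared
matrix uses centroid distances in meters, so its weights carry units of
m^-2; Moran's I is scale-free in the weights, so this does not affect I.

Centrography of the supply: the physician-weighted mean center; the
standard deviational ellipse from uncorrected weighted second moments
(axes reported with `sigma_x` the major axis, `theta_deg` the major-axis
orientation counterclockwise from east — an explicit convention, since
GIS packages differ); and the Clark–Evans nearest-neighbour index with
expected mean distance `0.5 * sqrt(A/n)` and standard error
`0.26136 / sqrt(n^2/A)`. The study-region area `A` is a modelling choice
the user must supply; no edge correction is applied, which biases the
index slightly upward for points near the boundary. Index < 1 indicates
clustering; the p-value is reported two-sided.

## The synthetic city generator

Real census, survey and clinic-registry inputs are restricted-access, so
the package ships a seeded generator (`generate_city()`) that emulates
their joint structure well enough to exercise every pipeline stage:

* **zones**: a rows × cols grid of square cells tiling a rectangle, with
  exact shared boundaries (so queen contiguity is unambiguous);
* **population**: per-zone totals drawn lognormal with median 542 and
  sdlog 0.3953 (mean ≈ 586) — the size regime of small census
  dissemination units — split over the nine age bins by a
  Dirichlet-multinomial around a fixed urban age profile shipped as a
  package file, so the users-to-population ratio is stable across seeds;
* **clinics**: a fraction `clinic_clustering` (default 0.8) drawn from a
  Gaussian around the rectangle center — the central business district —
  and the rest uniform; physician counts `1 + Poisson(lambda)`;
* **streets**: a connected grid network with edge length equal to the
  spacing.

The `montreal_like` preset fixes the scale: 45 × 70 = 3,150 zones of
390 m cells (about 483 km² total, ~0.15 km² per zone), 236 clinics with
`lambda = 1344/236 − 1` (≈ 5.7 physicians per clinic on average), CBD
standard deviation 3 km. Draw streams are re-seeded per component
(populations, locations, physician counts) so instances are reproducible
draw for draw from one integer seed.

What the generator does **not** emulate: irregular zone geometry and
area heterogeneity, water and other uninhabited gaps, anisotropic street
networks, spatially correlated age structure (the rich downtown/suburb
gradients of a real city), and supply just outside the study boundary.
Passing tests on synthetic cities therefore demonstrate the *method* —
conservation, monotone coverage, clustering recovered in kind — not
calibrated agreement with any real city's published accessibility
tables. Edge effects are flagged as a limitation, not corrected.

## Numerical choices

* Per-1,000 scaling is applied in step 1 (on `R_j`), so `A_i` magnitudes
  match the familiar "per 1,000 inhabitants" reporting scale.
* Both steps use the same `d0` by default; a mismatch errors unless
  explicitly allowed.
* Degenerate t-inputs (zero-variance `D` with non-zero mean) yield
  `t = ±Inf`, `p = 0`, flagged, rather than an error mid-report.
* Coincident points in the nearest-neighbour computation contribute zero
  distances with a warning (they are real data events, not errors);
  coincident centroids in the inverse-distance weights are an error
  naming the pair.
* The point-in-polygon boundary rule is inclusive, and a point on a
  shared boundary is assigned to exactly one zone so totals are
  preserved.

## Problem sizes in the test suite

The suite exercises the engine on ~50+ random instances of up to 60
zones × 15 clinics against the brute-force oracle, full-scale coverage
monotonicity on the 3,150-zone preset, pattern recovery (clinic NNI,
accessibility-vs-CBD-distance rank correlation, Moran's I of difference
scores) on a 576-zone clustered city, and byte-level determinism of the
complete reporting workflow on a 100-zone city. These sizes were chosen
so the whole suite runs in well under a minute while still hitting the
full-scale code paths.

## Known limitations

Binary catchments ignore within-catchment impedance; physician counts
proxy capacity without case-mix; utilization proportions are regional
averages applied uniformly over zones; edge effects at the study
boundary are flagged, not corrected; and GeoJSON layers are written with
planar-meter coordinates for a locally declared CRS, which round-trips
within this package but should be reprojected before mixing with
standard lon/lat GeoJSON.
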