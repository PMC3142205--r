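# twostepfca

Potential spatial accessibility of a population to clinics, measured
with the **two-step floating catchment area (2SFCA)** method — for
health-services researchers and planners who need to locate areas with
poor access to primary care, and to understand how much the answer
depends on how supply and demand are weighted.

## The method

Given clinics `j` and small demand zones `k` with a travel-distance
matrix `d_kj` (meters) and a catchment radius `d0`:

1. each clinic receives a supply-to-demand ratio per 1,000 persons over
   the population inside its catchment,

   `R_j = 1000 · S_j / Σ_{k : d_kj ≤ d0} D_k`

2. each zone sums the ratios of all clinics inside its own catchment,

   `A_i = Σ_{j : d_ij ≤ d0} R_j`

The **conventional** variant counts clinics (`S_j = 1`) against total
population `D_k`. The **optimized** variant weights supply by physician
counts `P_j` and demand by *potential users*
`W_k = Σ_x c_x · P_x` — zone populations by nine age groups, weighted by
age-specific past-year clinic-utilization proportions `c_x` (packaged
schedules for Montreal, Quebec and Canada ship with the package).
Zones with no clinic in range get a *missing* score, not zero; clinics
with empty catchments get an *undefined* ratio and contribute nothing.

Around the engine the package provides: Euclidean and street-network
(Dijkstra) distances, catchment construction, queen-contiguity and
inverse-distance-squared spatial weights, global Moran's I, centrography
(weighted mean center, standard deviational ellipse, Clark–Evans
nearest-neighbour index), method-comparison statistics (0–100 rescaling,
difference scores D, Spearman rank correlation, t-tests), CSV/GeoJSON
readers and writers, a full reporting workflow, and a seeded synthetic
city generator so everything runs reproducibly without restricted census
or clinic-registry data.

## Worked example

```r
library(twostepfca)

# a 100-zone synthetic city with 8 clinics clustered near the center
city <- generate_city(city_config(rows = 10, cols = 10, cell_size = 400,
                                  n_clinics = 8, clinic_clustering = 0.9,
                                  seed = 7))

conv <- fca(city$supply, city$demand, d0 = 1000, method = "conventional")
opt  <- fca(city$supply, city$demand, d0 = 1000, method = "optimized")
summary(opt)
#> 2SFCA accessibility, optimized method, d0 = 1000 m (euclidean)
#> zones: 100 (59 with access, 41 without)
#>
#> Accessibility scores (supply units per 1,000 persons):
#>       N    Mean      SD     Min     Max      P5     P25     P50     P75     P95
#> 59.0000  1.4020  0.8516  0.4379  3.3128  0.4830  0.7938  0.8475  1.9469  2.9836
```

59 of 100 zones have at least one clinic within 1 km; among them, a
resident can on average reach about 1.4 physicians per 1,000 potential
users. The 41 other zones are outside every catchment — missing, not
zero — which is exactly the bookkeeping a planner needs.

Comparing the two variants:

```r
cmp <- compare_methods(conv, opt)
cmp$spearman
#> rho = 0.971 (p = 5.3e-37, n = 59)
round(cmp$percentiles, 2)
#>   mean p_value    P5   P10   P25  P50  P75 P90  P95
#> 1  0.2    0.77 -8.53 -8.53 -4.01 1.23 4.88 6.2 6.62
```

The methods rank zones almost identically (rho = 0.97), but individual
zones differ by up to ±8 points on the 0–100 scale: positive D means
the conventional method over-estimates accessibility relative to the
optimized one. Are those differences spatially clustered?

```r
w <- queen_contiguity(city$zones)
d <- cmp$differences
morans_i(d$D, w[d$id, d$id])
#> Global Moran's I (queen weights)
#>   I = 0.6888  E[I] = -0.0172  z = 10.440  p = 1.631e-25  (n = 59, normality)

nearest_neighbour_index(city$supply, area = 4000^2)
#> Nearest-neighbour index (Clark-Evans)
#>   observed 591.6 m, expected 707.1 m, index = 0.837 (clustered)
#>   z = -0.884, p = 0.3768 (n = 8, A = 1.6e+07 m^2)
```

The measurement differences are strongly autocorrelated (I = 0.69,
z = 10.4): choosing the conventional over the optimized method does not
add noise, it adds *spatially structured* error concentrated in
particular neighbourhoods. The clinics themselves are clustered
(NNI < 1), as in real cities.

`run_report(city, "out/")` writes the whole apparatus at 500/1000/2000/
3000 m — per-zone scores, comparison tables, Spearman and difference
summaries, Moran's I under queen and inverse-distance-squared weights,
GeoJSON difference layers, and a machine-readable run log — all
byte-reproducible from the seed. A thin command-line wrapper lives in
`inst/scripts/fca_report.R` (subcommands `synth`, `access`, `report`).

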