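# walkshed

Intra-urban walking accessibility to healthcare, and the disparity between
formal and informal settlements.

## The problem

In many rapidly urbanizing cities, a large share of residents live in
informal settlements, and walking is the dominant — often the only — way
to reach a clinic or hospital. `walkshed` measures how long that walk is,
for whom, and how unequally it is distributed. It is aimed at spatial
epidemiologists and urban-health researchers who have, per city:

* a pedestrian street network (projected planar meters),
* healthcare facility points, grouped into hospitals/surgical-care
  (`group_i`) versus clinics and other facilities (`group_ii_other`),
* a fine (~5 m) land-use raster with six morphology classes
  (atomistic, informal subdivision, formal subdivision, housing project,
  open space, non-residential),
* a coarse (~100 m) gridded population raster, and
* a city boundary polygon.

## The model

Walking time from every location to its nearest facility is computed by a
multi-source shortest-path search on the street graph at walking speed *v*
(default 3.6 km/h, so 60 m = 1 minute), then rasterized: a cell's time is
the minimum over nearby network nodes of node time plus the straight-line
leg to the node at the same speed. This is the exact "dissolve" of
per-facility one-minute isochrones — overlapping service areas merge by
taking the minimum. Facilities within a 9 km buffer of the boundary count
(9 km is the rounded distance walkable in 2 h at 3.6 km/h + 20%).

The six land-use classes collapse to **informal** (atomistic + informal
subdivision), **formal** (formal subdivision + housing project) and
**other**. Population counts are disaggregated from the coarse grid onto
the fine grid (uniform within each coarse cell by default), and spatial
accessibility is

> SA_c(t) = share of class-c population whose travel time is ≤ t minutes,
> for t = 1..120,

with the residential classes (informal + formal) forming every
denominator. Speed is varied ±20% (factors 0.8/1.0/1.2) for uncertainty
brackets. Disparity at a threshold t is the relative risk

> RR(t) = SA_F(t) / SA_IF(t)  (coverage ratio; the exceedance variant
> (1 − SA_IF) / (1 − SA_F) is also reported),

with `[lo, hi]` the RR range over the speed factors and "significant"
meaning the whole interval exceeds 1. City sizes follow UN-Habitat classes
(small < 0.25 M, medium 0.25–1 M, large 1–5 M, very large ≥ 5 M).

Everything is testable offline: `generate_grid_city()`,
`generate_random_city()` and `two_cluster_disparity_city()` build complete
synthetic cities whose travel times and SA curves have closed forms.

## Worked example

```r
library(walkshed)
bundle <- generate_grid_city(n = 15, pop_per_node = 80)
run <- run_city(bundle, city_config(city_name = "grid_city"),
                out_dir = "results/grid_city")
print(run)
#> <city_run> grid_city (facility set: all)
#>   residential pop 14773 (informal share 0.841), outside 2 h 0.000
#>   surgical 2-h benchmark (hospitals): met
```

The 15×15 grid city has one central facility on a 60 m lattice, a formal
core and an informal ring; 14,773 residents live on residential land, 84.1%
of them in the informal ring. Everyone is within two hours' walk
(`outside 2 h 0.000`), and since the facility is a hospital the ≥80%-within-
2-h surgical-care benchmark is met. `results/grid_city/` then contains
`sa_curves.csv` (city, class, speed_factor, minute, share — 3 classes × 3
factors × 120 minutes), `rr_table.csv` (both RR variants at 15/30/60 min
with brackets and the significance flag), `summary.json` and `run.log`.

Published per-city summaries for 19 sub-Saharan African cities ship with
the package and flow through the same aggregation code:

```r
tab <- ssa19_city_summary()
s <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
  city_summary(tab$city[i], tab$total_pop_mio[i] * 1e6,
               tab$pct_informal[i] / 100,
               tab$n_facilities[i], tab$n_hospitals[i])))
aggregate_cities(s)
#> $total_pop             56930000
#> $pooled_informal_share 0.7191741
#> $n_facilities          5171
#> $size_class_counts     small 2, medium 6, large 7, very_large 4
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch against the
installed package — the deterministic grid city, a seeded random city, the
two-cluster disparity fixture, a multi-city pooled run, and the 19-city
aggregation — and writes its result map as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin wrapper lives at `inst/cli/walkshed-equity.R`:

```sh
Rscript inst/cli/walkshed-equity.R demo  --preset grid --out demo/
Rscript inst/cli/walkshed-equity.R synth --preset random --seed 1 --out bundle/
Rscript inst/cli/walkshed-equity.R run   --config city.yaml --inputs bundle/ --out results/
```

See `vignettes/walkshed-methods.Rmd` for the full account of the model,
its numerical choices and its limitations.
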