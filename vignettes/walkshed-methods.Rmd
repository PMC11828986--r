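---
title: "Methods: walking access to healthcare and settlement-type disparity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: walking access to healthcare and settlement-type disparity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkshed)
```

## The model

`walkshed` estimates, for every resident of a city, the walking time to the
nearest healthcare facility, and summarises how that time differs between
formal and informal residential settlement. The computation has four
stages.

**1. Network travel times.** The street network is an undirected weighted
graph in projected planar meters; an edge of length $\ell$ meters costs
$\ell / (1000\,v/60)$ minutes at walking speed $v$ km/h. Each facility is
snapped to its nearest network node within a snap radius (default 500 m;
ties go to the lowest node id) and carries an initial offset equal to its
straight-line distance to that node, converted to time at the same speed.
A multi-source shortest-path search seeded at all snapped facilities gives
every node its time to the *nearest* facility. This is mathematically the
dissolve of per-facility isochrones: overlapping service areas merge by
taking the pointwise minimum, which the multi-source search performs
implicitly and exactly. Nodes unreachable from every facility keep
$+\infty$ — never clipped to the 120-minute horizon, so "share outside
2 h" remains computable as $1 - SA(120)$.

**2. Rasterization.** Rather than constructing service-area polygons and
intersecting them with rasters (a geometrically fragile step), the travel
time is evaluated directly on the fine analysis grid: a cell's time is the
minimum over network nodes within the snap radius of node time plus the
euclidean leg from cell centroid to node, walked at the same speed. Cells
with no node in range are $+\infty$. The two representations agree wherever
both are defined, but the raster form makes the dissolve exact and is
verifiable cell by cell against an exhaustive scan, which the test suite
does.

**3. Population on land use.** The six morphology classes of the land-use
raster collapse to three: *informal* (atomistic + informal subdivision),
*formal* (formal subdivision + housing project) and *other* (open space,
non-residential, nodata — nodata never becomes residential, so neither
residential class is inflated). The coarse population raster is
disaggregated onto the fine grid by splitting each coarse cell's count
equally over the fine cells whose centroids it contains (mode
`uniform_all`, the default). A dasymetric alternative, `residential_only`,
splits over residential fine cells only, falling back to the cell's
`other` subcells (and logging it) when a coarse cell has no residential
subcell. Both modes conserve the source total. Grid misalignment is
resolved by centroid containment with half-open intervals — deterministic
and, at a 20:1 resolution ratio, a negligible approximation to area
weighting. A coarse cell only partially covered by the fine grid
concentrates its entire count on the covered part; population in coarse
cells with no covered fine cell at all is reported as `unallocated`.

**4. Accessibility and disparity.** Spatial accessibility for class $c$ is
$SA_c(t) = P(\text{travel time} \le t \mid c)$, evaluated at integer
minutes $t = 1..120$ (matching one-minute isochrone steps) with a closed
threshold — a resident exactly at $t$ minutes counts as covered, the
standard service-area convention; on synthetic data ties at integer
minutes are deliberate and resolved inclusively. The `other` class is
excluded from every denominator, so the "all" curve is the
population-weighted mean of the informal and formal curves by
construction. Disparity at threshold $t$ is the relative risk
$$RR(t) = SA_F(t) / SA_{IF}(t),$$
the coverage ratio, reported alongside the *exceedance* variant
$(1-SA_{IF})/(1-SA_F)$ — "how many times more likely is an informal
resident to exceed the threshold". Both cross 1 at the same locus
$SA_F = SA_{IF}$ and therefore agree in direction; the exceedance variant
matches the narrative reading of large disparities. The coverage ratio is
the default because it is the plainer definition; both appear side by side
in outputs.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `base_speed_kmh` | 3.6 | walking speed; 60 m per minute |
| `speed_factors` | 0.8, 1.0, 1.2 | ±20% sensitivity scenarios |
| `max_minutes` | 120 | isochrone horizon (2 h) |
| `thresholds_min` | 15, 30, 60 | reporting thresholds |
| `facility_set` | all | `all` facilities or `hospitals` (group_i) |
| `buffer_km` | 9 | boundary dilation for facility selection |
| `snap_radius_m` | 500 | facility→node and cell→node snap radius |
| `disaggregation_mode` | uniform_all | population splitting rule |
| `rr_variant` | coverage_ratio | default RR definition |

The 9-km buffer is the maximum distance walkable in 120 minutes at
3.6 km/h with a +20% speed margin (8.64 km), rounded to the nearest
kilometer; facilities just outside the boundary are thereby retained. An
alternative reading of the source material suggests 15 km; 9 km follows
the stated derivation and the value is configurable. The buffer is held
fixed across speed factors: the scenarios perturb travel time, not the
facility roster, so the `[lo, hi]` brackets isolate the speed effect.

Speed scenarios are computed by exact rescaling: because on-network and
off-network legs use the same speed, times at factor $f$ equal base times
divided by $f$, offsets included — identical to recomputation and tested
as such.

## Uncertainty intervals and significance

The RR interval at a threshold applies the *same* speed factor to both
classes (speed is a city-level perturbation, not a class-specific one),
yielding three RR values; `lo`/`hi` are their range and the point estimate
is the factor-1.0 value. `significant` is the entire-interval-above-one
rule; no multiple-testing correction is applied. If the RR is undefined in
*any* scenario (a zero denominator: zero informal coverage for the
coverage ratio, full formal coverage for the exceedance ratio), the whole
interval is flagged undefined rather than partially reported — a
noteworthy consequence is that a city can have a well-defined RR at base
speed that is still flagged, because the slow scenario leaves one class
uncovered. An RR of exactly 0 (formal coverage still zero while informal
coverage is positive) is a defined value and reported as such.

## The synthetic-data generators

`generate_grid_city()` builds a Manhattan lattice with 60-m edges at
3.6 km/h, so one edge is exactly one minute and every node's travel time
is an integer (the L1 lattice distance to the nearest facility) — no
floating-point path ambiguity, which is why the end-to-end tests can
demand exact recovery. Land use emulates the centre–periphery pattern of
many cities (formal core within a radius, informal ring outside, street
cells non-residential); population is deposited in the coarse cell
containing each lattice node (the generator deposits for every node — the
"residential node" notion is resolved at disaggregation, where street
cells are non-residential).

`generate_random_city()` draws a connected random geometric street graph
(regenerating up to a bounded number of attempts), uniform facilities, a
six-class land-use raster smoothed by a fixed two-pass 3×3 majority filter
(contiguous patches without a classifier), and log-normal population per
coarse cell. The default of ~150 persons per 100-m cell (meanlog
$\log 150$, sdlog 0.8) emulates dense urban gridded-population products
(~15,000/km²). Everything derives from one seed.

`two_cluster_disparity_city()` is a closed-form fixture: facility at the
origin of a single straight street, the formal cluster $t_F$ minutes east,
the informal cluster $t_{IF} = t_F + \text{gap}$ minutes west. Collinear
geometry matters: with a bent network, the rasterization's straight-line
leg could undercut the street distance and break the closed form (an
earlier design with perpendicular branches did exactly that). Each cluster
is a single residential fine cell centered on its node, so both SA curves
are exact unit steps and RR has a closed form per scenario. The gap snaps
to 1/12 minute so cluster nodes sit on 5-m cell centroids; geometry is
computed in integer 5-m units to keep coordinates exact in floating point.

What the generators do *not* emulate: real street-network topology
(one-ways, footpaths, severance), gridded-population error structure
(which in informal settlements can understate residents severalfold),
land-use classifier error, or facility-list incompleteness. A green test
therefore establishes that the *computation* is correct on a stated world,
not that real-city numbers are unbiased — on real inputs the results
inherit every upstream data limitation.

## Numerical choices

* Travel-time comparisons at thresholds reduce to `ceiling(minutes) <= t`,
  exact for the integer grid-city times; SA shares are clamped to
  $[0, 1]$ against the $\sim 10^{-15}$ tail of cumulative summation.
* Monotonicity of SA in the speed factor holds exactly in real arithmetic;
  in floats it holds up to summation order, and property tests assert it
  at $10^{-12}$.
* Facility snapping ties break to the lowest node id; coarse–fine grid
  assignment uses half-open intervals anchored at the grid origin. Both
  choices are arbitrary but deterministic.
* Rasters are exchanged as ESRI ASCII grids written with 17 significant
  digits, so doubles round-trip bit-exactly; GeoTIFF is deliberately not
  a dependency.
* Coordinates must arrive in projected planar meters. The package never
  reprojects: distances and speeds are metric, and a silent unit error
  would corrupt every downstream number, so layers whose bounding box
  looks like lon/lat degrees (within ±180/±90 with spans under 10) are
  refused outright. City-size class boundaries (0.25/1/5 million) are
  half-open with the boundary going to the larger class.
* Readers are otherwise permissive: records with missing coordinates or
  unmapped categories are skipped/defaulted and reported, never silently
  dropped.

## Degenerate inputs

An empty facility selection (e.g. a hospitals run in a city with no
group_i facility) is a warning, not an error: travel times are all
$+\infty$, SA curves are identically zero, the coverage RR is 0/0 and
flagged undefined, and the run completes. A class with zero population
yields an undefined-curve sentinel that propagates (NA shares, NA
benchmark). Disconnected network components unreachable from every
facility simply stay at $+\infty$ and appear in the outside-2-h share.

## Known limitations

Uniform walking speed (topography and surface quality enter only through
the ±20% scenarios); no facility capacity or demand competition (no
two-step floating catchment); no distance-decay indices; free traversal of
an undirected network; facility dedup is left to the caller (duplicate
points are retained by the readers). The multi-city pooled curves weight
by residential population, which assumes the per-city population bases are
comparable.
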