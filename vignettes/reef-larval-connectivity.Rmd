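---
title: "Modelling coral larval connectivity in a reef cluster"
author: "reefdrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coral larval connectivity in a reef cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Broadcast-spawning corals such as *Acropora* release gametes into the water
column on a few nights each year; the resulting larvae drift with the
currents for days to weeks before they are able to attach to reef substrate.
Which reefs exchange larvae — and which sites consistently act as sources or
sinks — determines how a reef cluster recovers from bleaching or cyclone
damage and where interventions (protected areas, outplanting of
heat-adapted corals) are best placed. `reefdrift` implements a complete
biophysical estimate of that connectivity: it regionalizes reef habitat
into site polygons, releases virtual larvae from each site, advects them
through gridded velocity fields, applies larval biology (competency,
mortality, instant settlement on suitable habitat), and summarises the
outcome as per-night site-by-site connectivity matrices and source/sink
classifications.

Because the velocity archives of a real hydrodynamic model are enormous and
site-specific, the package also ships an analytic synthetic environment —
drift + tide velocity fields, reef-platform bathymetry and hexagonal
habitat maps — so the entire analysis is reproducible and testable from
nothing. The synthetic generators are first-class, tested code, not
fixtures.

## Habitat regionalization

Habitat is supplied as a lattice of equal-area hexagons, each labelled with
one of four geomorphic zones (Reef Slope, Reef Crest, Sheltered Slope,
Outer Reef Flat) and a depth. Sites are built zone by zone:

1. **Adjacency.** The Delaunay triangulation of the zone's hexagon
   centroids defines the candidate merge graph. Triangulation, rather than
   nearest-neighbour adjacency, is used because a zone's patches are often
   spatially disjoint (a crest ring interrupted by channels); the Delaunay
   edge set of any planar point set is connected, so distant patches remain
   reachable.
2. **Weights.** Each edge gets the weight
   $w_{ij} = \sqrt{v_{ij}^2 + (d_i - d_j)^2}$, where $v_{ij}$ is the
   *normalized* centroid distance and $d_i, d_j$ are hexagon depths in
   metres. We normalize distances by the maximum centroid distance within
   the zone graph and leave depth differences in metres. The two terms are
   of different physical kinds, and the normalization convention genuinely
   matters: normalizing depth as well would change which splits are
   preferred in steep zones. We chose length-only normalization because it
   keeps the depth term interpretable (an edge across a 5 m depth step
   always costs at least 5) while bounding the geometric term; this is an
   assumption, recorded here deliberately.
3. **Spanning tree.** Kruskal's algorithm with ties broken by
   (weight, smaller id pair) gives a deterministic minimum spanning tree
   even on lattices where many edges share identical weights.
4. **Partition.** The tree is split into site polygons by iterative
   best-edge removal (a SKATER-style regionalization): at each step delete
   the tree edge whose removal most reduces within-cluster depth variance
   (sum of squared deviations), subject to both components keeping at
   least `min_size` hexagons; stop when no edge is deletable or the mean
   cluster area has reached `target_area`. The heterogeneity objective is
   depth alone — the weights already encode geometry, and depth is the
   habitat covariate the zones are meant to be homogeneous in. The number
   of sites is therefore an outcome, not an input; a zone component smaller
   than `min_size` stays a single site.

The reference values for a real survey-scale map are `min_size = 200`
hexagons and `target_area = 62,500` m². The synthetic two-platform domain
uses 26,000 m² hexagons and `min_size = 15` so the same machinery produces
a ten-site cluster at desk scale; this scaling changes no algorithmic
content.

## The biophysical model

**Release.** On each spawning night, every site releases one larva per
3-minute slot from 20:00 to 23:00 inclusive — 61 larvae per site per night
— at 2.25 m depth, at points drawn uniformly inside the site polygon
(rejection sampling against the hexagon lattice). With 334 sites this is
20,374 larvae per night.

**Advection.** Larvae are passive particles advected with a classical
4th-order Runge–Kutta step (5-minute default) through a nested sampler:
queries inside the fine (inner) grid use the fine field, elsewhere the
coarse (outer) field, with linear interpolation in time, bilinear in x–y
and linear in z between layer centres. Vertical motion is advection by `w`
only (neutral buoyancy) with reflective boundaries at the surface and the
local seabed. Leaving the fine grid is not removal — particles may return —
but any particle sampling outside the *coarse* domain is removed as
`exited`. A particle whose update lands in a land cell keeps its previous
position for that step; there is no explicit diffusion and no behavioural
swimming. Positions are recorded every 15 minutes.

The integrator and interpolation order are modelling choices of this
package (typical of Lagrangian tracking tools); RK4 on a solid-body
rotation closes an orbit with the expected 4th-order error decay (~16×
per halving of the step), which the tests verify.

**Biology.** A larva may settle from 4 to 28 days after its own release
(ages are per-particle; releases span three hours). Settlement is checked
at every 15-minute record point: the first record inside any site polygon
during the competency window settles the larva instantly on that site —
including its natal site, so self-recruitment is possible — and tracking
ceases. Mortality removes 40 % of the night cohort's remaining larvae at
every whole day after the release window opens,
`round(0.40 × n_active)` individuals drawn uniformly without replacement,
before that day's settlement checks. Two readings of "40 % per day" exist:
removing 40 % of the *original* cohort daily would extinguish the cohort by
day 3, before the competency window even opens, so the remaining-larvae
reading is the only one consistent with settlement occurring at all.
Thinning is applied to the night cohort as a set (not per particle as a
Bernoulli trial): with the 3-minute release stagger, per-particle daily
groups would contain a single larva and `round(0.4 × 1) = 0` would never
remove anything.

**Timing discretization.** Releases fall on a 3-minute cadence while the
integrator steps every 5 minutes; a larva enters the simulation at the
first global step boundary at or after its nominal release time and is
recorded on the global 15-minute grid. The quantization is at most 5
minutes — centimetres-per-second flows move a particle metres in that time,
far below the grid resolution.

## Connectivity summaries

For night $k$, the connectivity matrix entry $M_{ij}$ is the proportion of
larvae released at source site $i$ that settled at sink site $j$. Row sums
are at most 1 by construction; column sums may exceed 1 (a site can receive
from many sources). From the matrices the package derives:

- `pct_settled` — 100 × settled / released;
- `pct_sink_sites` — the share of sites with positive column sum (the
  denominator is *all* sites, a deliberate choice since "suitable that
  night" is not otherwise defined);
- `count_links` — strictly positive entries, diagonal included
  (self-recruitment is a cyclic link);
- `source_sink_summary` — row sums (source strength), column sums (sink
  strength), diagonal (self-recruitment);
- `consistency` — a site is a consistent source (sink) if its source (sink)
  strength is positive on **every** analysed night;
- `compare_dimensions` — percentage change in links and sink counts
  between velocity modes, undefined when the reference count is zero.

## The synthetic environment

`make_drift_tide_field()` produces
`u(t, k) = shear[k] · (mean_u + A · sin(2πt/T))` (likewise `v`; `w = 0`):
a steady drift with a tidal oscillation, vertically scaled by per-layer
multipliers. Its time average over whole tidal periods is exactly the mean
drift, per layer. Bathymetry is a deep background with smooth-sided reef
platforms; the land mask is `depth ≤ 0` and velocities are zeroed on land.
Hexagon maps place an interior reef flat, a crest ring one ring in from
the edge, and an outer ring split into exposed/sheltered slopes, with depth
monotone in ring distance from the crest plus seeded metre-scale noise.

Two study configurations are frozen in `reef_cluster_scenario()`:

- **drift** — westward mean drift −0.015 m/s, M2 tide (12.42 h) of
  0.10 m/s, no vertical shear; two platforms ~5.9 km apart. A larva from
  the eastern platform transits the gap in ≈4.5 days, inside its
  competency window as it crosses the western platform, so east sites are
  consistent sources and west sites consistent sinks.
- **shear** — eastward surface drift 0.15 m/s confined to a thin 0.45 m
  surface layer (shear multipliers 1, 0.01, 0.005), mild tide. Surface-2D
  tracking sweeps every larva out of the domain before competency; full-3D
  tracking at the 2.25 m release depth retains larvae over their natal
  platform. This reproduces, qualitatively, the sensitivity of connectivity
  to the dimension of the velocity fields.

Layer interfaces are (0, 0.45, 4.05, 45) m. The vertical resolution larvae
experience in real models is unspecified territory; we use a thin surface
layer (as reef-scale models do) and place the second layer's centre exactly
at the 2.25 m release depth, so a neutrally buoyant larva samples that
layer's velocity without blending from the surface jet. Platform crests sit
at 3 m depth so the release depth is always submerged and no seabed
reflection occurs at release.

What the generators deliberately do **not** emulate: mesoscale eddies, reef
wakes, wind bursts, baroclinic vertical velocities, wetting/drying, or
curvilinear grids. Passing tests on these fields therefore demonstrate the
correctness of the machinery (interpolation, integration, bookkeeping,
statistics), not skill against field observations.

## Numerical choices and degenerate inputs

- Hexagon centroids are maximally degenerate for Delaunay triangulation
  (co-circular quadruples everywhere); a deterministic symbolic jitter of
  relative size 1e-8 breaks ties, and edges/areas are reported from the
  unjittered coordinates. Fully collinear inputs fall back to a chain
  graph.
- Point-in-polygon tests go through the exact lattice inverse (cube
  rounding), so containment is boundary-inclusive up to deterministic
  assignment of boundary points to the nearest centre.
- The MST and the partition tie-break on (weight/reduction, smallest id
  pair), making every regionalization reproducible.
- `round()` (banker's rounding) defines the mortality count; a cohort of
  one larva never dies (`round(0.4) = 0`), and iterated thinning stays
  within ±d of `N·0.6^d` after d days.
- Degenerate inputs rejected with messages: non-positive tidal period,
  shear length mismatches, zero platform radius, duplicate centroids,
  zero released counts, records referencing unknown sites, empty sites.

## Problem sizes

The shipped analyses and checks use the two-platform domain (254 hexagons,
10 sites, 610 larvae per night), three consecutive spawning nights, and a
10-day tracking horizon for the drift scenario (6 days for the retention
scenario, where settlement concludes shortly after competency opens).
These sizes were chosen so the directional and sensitivity analyses can be
replicated over 100 seeds; the machinery itself is size-independent and
the 30-day, 334-site reference protocol is the package default
(`tracker_config()`, `build_release_schedule()`).

## Known limitations

- No larval behaviour beyond neutral buoyancy: no swimming, substrate
  exploration, settlement delay after contact, or buoyancy ontogeny.
- Mortality is age-independent; competency is a hard window.
- Rectilinear grids only; no diffusion kernel, so sub-grid dispersion is
  not represented.
- Consistency classification is binary (positive on all nights); with many
  nights a single calm night can demote an otherwise strong source.
- The synthetic fields are kinematic: they impose flow structure rather
  than solving for it, so absolute settlement percentages from the demo
  scenarios characterise the scenarios, not any real reef.
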