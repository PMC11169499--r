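# reefdrift

Biophysical modelling of coral larval dispersal and connectivity within a
reef cluster, in R.

Reef recovery after bleaching and cyclones depends on where coral larvae
come from and where they settle. `reefdrift` estimates that exchange for
broadcast-spawning corals as a complete pipeline:

1. **Regionalization** — partition a hexagonal habitat map (four geomorphic
   zones: Reef Slope, Reef Crest, Sheltered Slope, Outer Reef Flat) into
   reef *site polygons*: per-zone Delaunay adjacency over hexagon
   centroids, edge weights `w_ij = sqrt(v_ij^2 + (d_i - d_j)^2)` combining
   the normalized edge length with the depth difference, a deterministic
   Kruskal minimum spanning tree, and size-constrained tree splitting
   (minimum 200 hexagons per site, ~62,500 m² target area at survey
   scale).
2. **Lagrangian tracking** — virtual larvae released from every site
   (61 per site per night, every 3 minutes from 20:00 to 23:00, at 2.25 m
   depth) are advected as passive particles by 4th-order Runge–Kutta
   through nested fine/coarse gridded velocity fields, in surface-2D,
   depth-averaged-2D or full-3D mode, with a 5-minute step and 15-minute
   position records over up to 30 days. Particles leaving the outer domain
   are removed; leaving the inner grid is not removal.
3. **Larval biology** — competency from 4 to 28 days post-release, 40 %
   daily mortality of the remaining cohort, and instant settlement on the
   first site polygon a competent larva's recorded position falls inside
   (natal site included).
4. **Connectivity** — per-night site×site matrices `M[i, j]` = proportion
   of larvae released at `i` that settled at `j` (row sums ≤ 1, column
   sums unbounded), settlement and sink-site percentages, link counts
   (self-loops included), source/sink strengths, *consistent* source/sink
   classification (positive on every analysed night), and comparisons of
   link/sink counts between velocity modes.

Everything runs on synthetic environments built by the package — analytic
drift + tide velocity fields with per-layer shear, reef-platform
bathymetry, and hexagon habitat maps — so the full analysis is reproducible
without any hydrodynamic model archive. Velocity fields and trajectories
read/write NetCDF; maps and site polygons GeoJSON; matrices and tables CSV;
networks GraphML.

## Worked example

Two reef platforms ~5.9 km apart under a westward drift (−0.015 m/s) with
an M2 tide; three spawning nights tracked for 10 days:

```r
library(reefdrift)

sc <- reef_cluster_scenario("drift")   # map, sites, nested velocity fields
mats <- lapply(1:3, function(ni)
  run_night(sc$sites, sc$samplers$depthavg2d,
            night_start = (ni - 1) * 24, night_id = ni,
            mode = "depthavg2d", duration_days = 10, seed = 1)$matrix)
sapply(mats, pct_settled)
#> [1] 7.049180 6.229508 6.229508
sapply(mats, count_links)
#> [1] 12 16 14
consistency(mats)[, c("site_id", "consistent_source", "consistent_sink")]
```

Sites 1–5 (the eastern platform) are consistent sources and sites 6, 9, 10
(western platform) consistent sinks: with a ~4.5-day transit across the
platform gap, eastern larvae arrive over the western platform inside their
4–28-day competency window, while western larvae drift into open water.
About 6–7 % of released larvae settle each night — the rest die (40 %/day)
or miss the habitat.

The numbered scripts under `analysis/` run the same study end to end and
write their tables under `results/`:

```sh
Rscript analysis/01_environment.R    # domain, fields, bathymetry
Rscript analysis/02_regionalize.R    # site polygons
Rscript analysis/03_track_nights.R   # 3 nights x 2 modes -> matrices
Rscript analysis/04_connectivity.R   # consistency, directionality, network
Rscript analysis/05_sensitivity.R    # surface-2D vs full-3D link counts
```

Step 5 uses the complementary "shear" scenario (an eastward surface jet
over a nearly still sub-surface): surface-2D tracking exports every larva
before competency (0 % settlement), while full-3D tracking at the 2.25 m
release depth retains ~9 % to settlement — full-3D yields at least as many
links as surface-2D in 20 of 20 seeds.

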