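#!/usr/bin/env Rscript
# Step 1 — build the synthetic study domain.
#
# Constructs the two-reef hexagonal habitat map and the nested fine/coarse
# drift + tide velocity fields, and exports the environment products
# (hexagon map GeoJSON, velocity/bathymetry NetCDF) under results/.

library(reefdrift)
dir.create("results", showWarnings = FALSE)

sc <- reef_cluster_scenario("drift", n_hours = 312)

cat("Hexagon habitat map:\n")
print(sc$map)
cat("\nHexagons per zone and platform (ids < 1000 = east platform):\n")
print(table(zone = sc$map$hexes$zone, platform = ifelse(sc$map$hexes$id < 1000,
                                                        "east", "west")))
cat("\nDepth by ring (distance from platform centre), east platform:\n")
east <- sc$map$hexes[sc$map$hexes$id < 1000, ]
print(round(tapply(east$depth, east$ring, mean), 2))

write_hexmap_geojson(sc$map, "results/hexmap.geojson")
write_velocity_nc(sc$fine3d, "results/velocity_fine3d.nc")
write_velocity_nc(sc$coarse3d, "results/velocity_coarse3d.nc")

# time-mean flow check: the tidal component cancels over whole periods
u_mean <- mean(sc$fine3d$u[1, 1, 1, 1:298])   # ~24 M2 periods of 12.42 h
cat(sprintf("\nTime-mean surface u over ~24 tidal periods: %.4f m/s (drift -0.015)\n",
            u_mean))
cat("Wrote results/hexmap.geojson, results/velocity_{fine3d,coarse3d}.nc\n")
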