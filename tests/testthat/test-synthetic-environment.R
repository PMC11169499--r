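test_that("drift-tide field matches its analytic definition", {
  g <- grid_spec(seq(0, 1000, 500), seq(0, 1000, 500), c(0, 5), seq(0, 24))

  f <- make_drift_tide_field(g, mean_u = -0.1, tidal_amp = 0, shear = 1)
  expect_true(all(f$u == -0.1))
  expect_true(all(f$v == 0))

  f <- make_drift_tide_field(g, mean_u = 0, tidal_amp = 0.3,
                             tidal_period = 12, shear = 1)
  expect_equal(f$u[1, 1, 1, 1], 0)                      # sin(0)
  expect_equal(f$u[1, 1, 1, 7], 0, tolerance = 1e-12)   # t = 6 h, sin(pi)
  expect_equal(f$u[1, 1, 1, 4], 0.3)                    # t = 3 h, sin(pi/2)

  g3 <- grid_spec(seq(0, 1000, 500), seq(0, 1000, 500), c(0, 1, 2, 5),
                  seq(0, 24))
  f3 <- make_drift_tide_field(g3, mean_u = -0.1, tidal_amp = 0.2,
                              tidal_period = 12, shear = c(1, 0.5, 0))
  expect_true(all(f3$u[, , 3, ] == 0))
  expect_equal(f3$u[, , 2, ], f3$u[, , 1, ] / 2, tolerance = 1e-12)

  expect_error(make_drift_tide_field(g, tidal_period = 0), "tidal_period")
  expect_error(make_drift_tide_field(g3, shear = c(1, 1)), "per layer")
})

test_that("time-average over whole tidal periods recovers the mean drift", {
  g <- grid_spec(seq(0, 1000, 500), seq(0, 1000, 500), c(0, 1, 5),
                 seq(0, 48))
  f <- make_drift_tide_field(g, mean_u = -0.08, mean_v = 0.03,
                             tidal_amp = 0.25, tidal_period = 12,
                             shear = c(1, 0.4))
  # integrate u(t) over 4 whole periods with the trapezoid rule on the
  # hourly snapshots (snapshots resolve the 12 h sine exactly enough)
  trap <- function(v) (sum(v) - (v[1] + v[length(v)]) / 2) / (length(v) - 1)
  for (k in 1:2) {
    sh <- c(1, 0.4)[k]
    expect_equal(trap(f$u[1, 1, k, ]), sh * -0.08, tolerance = 1e-10)
    expect_equal(trap(f$v[1, 1, k, ]), sh * 0.03, tolerance = 1e-10)
  }
})

test_that("reef bathymetry places platforms in a deep background", {
  g <- grid_spec(seq(-5000, 5000, 250), seq(-5000, 5000, 250), c(0, 45),
                 0:1)
  b0 <- make_reef_bathymetry(g, list(), 45)
  expect_true(all(b0$depth == 45))

  b <- make_reef_bathymetry(g, list(list(centre = c(0, 0), radius = 1000,
                                         crest_depth = 2)), 45)
  expect_equal(min(b$depth), 2)
  ic <- which(g$x == 0)
  expect_equal(b$depth[ic, ic], 2)            # platform centre on the crest
  expect_equal(b$depth[1, 1], 45)             # far corner at background
  expect_true(all(diff(b$depth[ic:length(g$x), ic]) >= 0))  # monotone ramp

  expect_error(make_reef_bathymetry(g, list(list(centre = c(0, 0),
                                                 radius = 0,
                                                 crest_depth = 2))),
               "radius")
})

test_that("hexagon map counts, areas and zones follow the closed forms", {
  for (n in c(1, 2, 5)) {
    m <- make_hexagon_map(n, hex_area = 1000)
    expect_equal(nrow(m$hexes), 1 + 3 * n * (n + 1))
    expect_equal(nrow(m$hexes) * m$hex_area,
                 length(m$hexes$id) * 1000)
  }
  m <- make_hexagon_map(6, hex_area = 26000)
  expect_true(all(m$hexes$zone %in%
                    c("ReefSlope", "ReefCrest", "ShelteredSlope",
                      "OuterReefFlat")))
  expect_equal(length(unique(m$hexes$zone)), 4)
  # default depth rule is monotone in ring distance from the crest ring
  crest <- 5
  expect_gte(cor(m$hexes$depth, abs(m$hexes$ring - crest)), 0)
  # neighbouring centroids are sqrt(3) * circumradius apart
  d01 <- sqrt((m$hexes$x[1] - m$hexes$x[2])^2 +
              (m$hexes$y[1] - m$hexes$y[2])^2)
  expect_equal(d01, sqrt(3) * m$size, tolerance = 1e-9)
})

test_that("zone rules can produce spatially non-contiguous zone patches", {
  ring_skip <- function(ring, n_rings, x, y) {
    z <- rep("OuterReefFlat", length(ring))
    z[ring %in% c(0, 2)] <- "ReefCrest"   # crest on rings 0 and 2 only
    z[ring == 1] <- "OuterReefFlat"
    z[ring > 2] <- "ReefSlope"
    z
  }
  m <- make_hexagon_map(3, 1000, zone_rule = ring_skip)
  crest <- m$hexes[m$hexes$zone == "ReefCrest", ]
  expect_setequal(unique(crest$ring), c(0, 2))
  # the two crest patches are separated by the ring-1 annulus
  expect_gt(min(crest$ring[crest$ring > 0]) - max(crest$ring[crest$ring < 2]), 1)
})

test_that("surface extraction preserves layer 1 bit-exactly", {
  g3 <- grid_spec(seq(0, 2000, 500), seq(0, 2000, 500), c(0, 1, 3, 10),
                  seq(0, 12))
  f3 <- make_drift_tide_field(g3, mean_u = -0.1, tidal_amp = 0.2,
                              tidal_period = 6, shear = c(1, 0.5, 0.1))
  fs <- derive_surface(f3)
  expect_identical(fs$mode, "surface2d")
  expect_identical(fs$u[, , 1, ], f3$u[, , 1, ])
  expect_identical(fs$v[, , 1, ], f3$v[, , 1, ])
  expect_error(derive_surface(fs), "full3d")
})

test_that("depth averaging is the thickness-weighted mean above the seabed", {
  g3 <- grid_spec(seq(0, 2000, 500), seq(0, 2000, 500), c(0, 1, 2, 4), 0:2)
  nx <- 5; ny <- 5
  mk_field <- function(per_layer_u) {
    u <- array(rep(per_layer_u, each = nx * ny), c(nx, ny, 3, 3))
    v <- array(0, c(nx, ny, 3, 3)); w <- array(0, c(nx, ny, 3, 3))
    velocity_field_set(g3, u, v, w, mode = "full3d")
  }
  deep <- make_reef_bathymetry(g3, list(), 4)

  # depth-uniform profile: average equals the profile, and equals the surface
  fu <- mk_field(c(0.3, 0.3, 0.3))
  expect_equal(derive_depth_averaged(fu, deep)$u,
               derive_surface(fu)$u, tolerance = 1e-14)

  # two equal-thickness wet layers with u = 1 and 0 -> 0.5
  shallow2 <- make_reef_bathymetry(g3, list(), 4)
  shallow2$depth[] <- 2
  f2 <- mk_field(c(1, 0, 7))       # third layer is below the 2 m seabed
  expect_equal(unique(as.vector(derive_depth_averaged(f2, shallow2)$u)), 0.5)

  # thickness 1,1,2 with u = 1,1,0 -> (1*1 + 1*1 + 2*0) / 4 = 0.5
  f3 <- mk_field(c(1, 1, 0))
  expect_equal(unique(as.vector(derive_depth_averaged(f3, deep)$u)), 0.5)

  # zero water column -> land with zero velocity
  dry <- make_reef_bathymetry(g3, list(), 4)
  dry$depth[1, 1] <- 0
  fd <- derive_depth_averaged(mk_field(c(1, 1, 1)), dry)
  expect_true(fd$land_mask[1, 1])
  expect_equal(fd$u[1, 1, 1, ], c(0, 0, 0))
})

test_that("velocity fields and hexagon maps round-trip through files", {
  g3 <- grid_spec(seq(0, 2000, 500), seq(0, 1000, 500), c(0, 1, 5), 0:3)
  f3 <- make_drift_tide_field(g3, mean_u = -0.1, tidal_amp = 0.1,
                              tidal_period = 6, shear = c(1, 0.3))
  nc <- tempfile(fileext = ".nc")
  write_velocity_nc(f3, nc)
  f3b <- read_velocity_nc(nc)
  expect_equal(f3b$u, f3$u, tolerance = 1e-12)
  expect_equal(f3b$grid$layer_interfaces, g3$layer_interfaces)
  expect_identical(f3b$mode, "full3d")

  m <- make_hexagon_map(2, 26000, depth_noise_sd = 0.3, seed = 4)
  gj <- tempfile(fileext = ".geojson")
  write_hexmap_geojson(m, gj)
  m2 <- read_hexmap_geojson(gj)
  expect_equal(m2$hexes$zone, m$hexes$zone)
  expect_equal(m2$hexes$depth, m$hexes$depth, tolerance = 1e-9)
  expect_equal(m2$size, m$size, tolerance = 1e-9)
  expect_equal(m2$hexes$x, m$hexes$x, tolerance = 1e-9)
})
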