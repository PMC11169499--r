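test_that("velocity sampling reproduces nodal values and interpolates linearly", {
  # field varying only in time: u = 0 at t=0, 1 at t=1
  g <- grid_spec(seq(0, 1000, 500), seq(0, 1000, 500), c(0, 5), 0:1)
  u <- array(rep(c(0, 1), each = 9), c(3, 3, 1, 2))
  v <- array(0.25, c(3, 3, 1, 2))
  f <- velocity_field_set(g, u, v, mode = "depthavg2d")
  big <- grid_spec(seq(-5000, 5000, 1000), seq(-5000, 5000, 1000), c(0, 5),
                   0:1)
  fc <- velocity_field_set(big, array(2, c(11, 11, 1, 2)),
                           array(0.25, c(11, 11, 1, 2)), mode = "depthavg2d")
  smp <- nested_velocity_sampler(f, fc)

  s <- sample_velocity(smp, 500, 500, 0, 0)     # fine grid node, snapshot
  expect_equal(s$u, 0)
  expect_equal(s$v, 0.25)
  s <- sample_velocity(smp, 500, 500, 0, 0.5)   # time midpoint
  expect_equal(s$u, 0.5)
  # inside fine bounds the fine field wins over the disagreeing coarse field
  s <- sample_velocity(smp, 250, 750, 0, 0)
  expect_equal(s$u, 0)
  # outside fine bounds the coarse field is used
  s <- sample_velocity(smp, 3000, 0, 0, 0)
  expect_equal(s$u, 2)
  # outside the coarse bounds the query is flagged
  s <- sample_velocity(smp, 9000, 0, 0, 0)
  expect_false(s$inside)
  expect_true(is.na(s$u))
})

test_that("compiled sampling agrees with the R reference step for step", {
  flds <- uniform_flow_fields(u0 = 0.05, du_dy = 2e-5, n_hours = 6)
  x0 <- c(-1500, 0, 900, 2500); y0 <- c(-300, 140, 1100, -2200)
  r_step <- step_rk4(x0, y0, rep(0, 4), 0.4, flds$nested, 5)
  packed <- reefdrift:::pack_sampler(flds$nested)
  cpp <- reefdrift:::advance_particles_cpp(x0, y0, rep(0, 4), rep(0L, 4),
                                           0.4, 1L, 300,
                                           packed$fine, packed$coarse, FALSE)
  expect_equal(cpp$x, r_step$x, tolerance = 1e-12)
  expect_equal(cpp$y, r_step$y, tolerance = 1e-12)
})

test_that("RK4 is exact on constant flow and 4th-order on rotation", {
  flds <- uniform_flow_fields(u0 = 0.1, n_hours = 3)
  s <- step_rk4(0, 0, 0, 0, flds$nested, 60)
  expect_equal(s$x, 360)          # 0.1 m/s for 1 h, RK4 exact
  expect_equal(s$y, 0)

  rot <- rotation_sampler(6)      # one revolution per 6 h
  closure_err <- function(dt_min) {
    n <- round(6 * 60 / dt_min); x <- 1000; y <- 0; t <- 0
    for (i in seq_len(n)) {
      s <- step_rk4(x, y, 0, t, rot, dt_min)
      x <- s$x; y <- s$y; t <- t + dt_min / 60
    }
    sqrt((x - 1000)^2 + y^2)
  }
  errs <- vapply(c(20, 10, 5), closure_err, numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 12 & ratios < 20))
})

test_that("particles exiting the outer domain are removed as exited", {
  flds <- uniform_flow_fields(u0 = 0.1, n_hours = 48)
  parts <- data.frame(particle_id = 1:2, source_site = 1L,
                      x = c(9000, 0), y = 0, z = 0, release_time = 0)
  cfg <- tracker_config(duration_days = 1, mode = "depthavg2d")
  tr <- track(parts, flds$nested, cfg)
  expect_equal(tr$status_label[1], "exited")
  # no recorded position of particle 1 lies outside the coarse bounds
  expect_true(all(abs(tr$x[1, ]) <= 10000, na.rm = TRUE))
  # particle 2 drifts 8.64 km in 24 h and stays inside, still active
  expect_equal(tr$status_label[2], "active")
})

test_that("tracking records on the 15-min cadence and honours hooks", {
  flds <- uniform_flow_fields(u0 = 0, n_hours = 30)
  parts <- data.frame(particle_id = 1L, source_site = 1L, x = 123, y = -45,
                      z = 0, release_time = 0)
  cfg <- tracker_config(duration_days = 1, mode = "depthavg2d")
  tr <- track(parts, flds$nested, cfg)
  expect_equal(length(tr$times), 96)                 # 24 h / 15 min
  expect_true(all(tr$x[1, ] == 123 & tr$y[1, ] == -45))

  # westward drift 0.1 m/s for 24 h -> 8640 m west
  fw <- uniform_flow_fields(u0 = -0.1, n_hours = 30)
  parts2 <- data.frame(particle_id = 1L, source_site = 1L, x = 5000, y = 0,
                       z = 0, release_time = 0)
  tr2 <- track(parts2, fw$nested, cfg)
  expect_equal(tr2$x[1, 96] - 5000, -8640, tolerance = 1e-6)

  # a hook that settles everything at the first record
  hook <- function(df, t_now)
    data.frame(particle_id = df$particle_id, status = "settled",
               settle_site = 99L)
  tr3 <- track(parts2, fw$nested, cfg, settlement_hook = hook)
  expect_equal(tr3$status_label, "settled")
  expect_equal(tr3$settle_site, 99L)
  expect_equal(sum(!is.na(tr3$x[1, ])), 1)           # one record then stopped
  expect_equal(tr3$status_time, tr3$times[1])
})

test_that("release times are honoured per particle", {
  flds <- uniform_flow_fields(u0 = -0.1, n_hours = 30)
  parts <- data.frame(particle_id = 1:2, source_site = 1L, x = 5000, y = 0,
                      z = 0, release_time = c(0, 12))
  cfg <- tracker_config(duration_days = 1, mode = "depthavg2d")
  tr <- track(parts, flds$nested, cfg)
  # particle 2 has no records before its release at t = 12 h
  expect_true(all(is.na(tr$x[2, tr$times <= 12])))
  half_day_later <- which(tr$times > 12)
  expect_equal(tr$x[2, half_day_later[length(half_day_later)]] - 5000,
               -0.1 * 12 * 3600, tolerance = 1e-6)
  expect_error(
    track(data.frame(particle_id = 1L, source_site = 1L, x = 0, y = 0,
                     z = 0, release_time = 50), flds$nested, cfg),
    "outside the simulated window")
})

test_that("nested fine/coarse handoff matches the single-grid solution", {
  # linear-in-y flow is represented exactly by bilinear sampling on both
  # grids, so the nested trajectory must match the coarse-only one
  flds <- uniform_flow_fields(u0 = 0.15, v0 = 0.02, du_dy = 5e-5,
                              n_hours = 30)
  parts <- data.frame(particle_id = 1L, source_site = 1L, x = -1500,
                      y = -800, z = 0, release_time = 0)
  cfg <- tracker_config(duration_days = 1, mode = "depthavg2d")
  tr_n <- track(parts, flds$nested, cfg)
  tr_c <- track(parts, flds$coarse_only, cfg)
  # the particle starts inside the fine domain and leaves it mid-run
  expect_true(any(abs(tr_n$x[1, ]) > 2000, na.rm = TRUE))
  expect_equal(tr_n$x, tr_c$x, tolerance = 1e-9)
  expect_equal(tr_n$y, tr_c$y, tolerance = 1e-9)
})

test_that("a particle stepping onto land holds its position and stays active", {
  g <- grid_spec(seq(0, 4000, 500), seq(0, 2000, 500), c(0, 10), 0:30)
  depth <- matrix(20, 9, 5); depth[8:9, ] <- 0      # land wall at x >= 3500
  bathy <- structure(list(grid = g, depth = depth),
                     class = "bathymetry_field")
  f <- make_drift_tide_field(g, mean_u = 0.2, bathy = bathy,
                             mode = "depthavg2d")
  gc <- grid_spec(seq(-8000, 8000, 1000), seq(-4000, 6000, 1000), c(0, 10),
                  0:30)
  fc <- make_drift_tide_field(gc, mean_u = 0.2, mode = "depthavg2d")
  smp <- nested_velocity_sampler(f, fc)
  parts <- data.frame(particle_id = 1L, source_site = 1L, x = 1000, y = 1000,
                      z = 0, release_time = 0)
  cfg <- tracker_config(duration_days = 1, mode = "depthavg2d")
  tr <- track(parts, smp, cfg)
  expect_equal(tr$status_label, "active")
  # the particle never penetrates the land wall
  expect_true(all(tr$x[1, ] < 3500, na.rm = TRUE))
  # but it did move towards it before stalling in the velocity shadow
  expect_gt(max(tr$x[1, ], na.rm = TRUE), 2000)
})

test_that("status accounting satisfies the conservation identity", {
  flds <- uniform_flow_fields(u0 = 0.5, n_hours = 48)
  set.seed(5)
  parts <- data.frame(particle_id = 1:30, source_site = 1L,
                      x = runif(30, -9000, 9000), y = runif(30, -9000, 9000),
                      z = 0, release_time = 0)
  hook <- function(df, t_now) {
    pick <- df$particle_id[df$particle_id %% 7 == 0]
    if (!length(pick)) return(NULL)
    data.frame(particle_id = pick, status = "settled", settle_site = 1L)
  }
  tr <- track(parts, flds$nested,
              tracker_config(duration_days = 1, mode = "depthavg2d"),
              settlement_hook = hook)
  acc <- accounting(tr)
  expect_equal(acc[["released"]],
               acc[["active"]] + acc[["settled"]] + acc[["dead"]] +
                 acc[["exited"]])
  expect_gt(acc[["exited"]], 0)
  expect_gt(acc[["settled"]], 0)
})

test_that("trajectories round-trip through NetCDF", {
  flds <- uniform_flow_fields(u0 = -0.05, n_hours = 30)
  parts <- data.frame(particle_id = 1:3, source_site = c(1L, 1L, 2L),
                      x = c(0, 500, 1000), y = 0, z = 0, release_time = 0)
  tr <- track(parts, flds$nested,
              tracker_config(duration_days = 1, mode = "depthavg2d"))
  nc <- tempfile(fileext = ".nc")
  write_trajectories_nc(tr, nc)
  back <- read_trajectories_nc(nc)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$times, tr$times)
  expect_equal(back$status, tr$status)
  expect_equal(back$source_site, tr$particles$source_site)
})
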