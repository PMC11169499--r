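#' Nested fine/coarse velocity sampler
#'
#' Couples a fine inner velocity field to a coarse outer field, the way a
#' high-resolution reef-cluster domain is nested inside a regional model:
#' queries inside the fine bounds sample the fine field, queries outside the
#' fine bounds but inside the coarse bounds sample the coarse field, and
#' queries outside the coarse bounds are "outside the domain" (a tracked
#' particle there is removed as exited). Interpolation is linear in time,
#' bilinear in x-y and linear in z between layer centres (3D mode), so nodal
#' values at grid points and snapshot times are reproduced exactly.
#'
#' @param fine Inner [velocity_field_set()] (`NULL` for a single-grid
#'   sampler).
#' @param coarse Outer [velocity_field_set()]; must share the fine field's
#'   mode, and the fine bounds must lie strictly inside the coarse bounds.
#' @param fine_bathy,coarse_bathy Optional [make_reef_bathymetry()] fields on
#'   the matching grids, used for seabed reflection of vertical motion.
#' @return An object of class `nested_sampler`.
#' @export
nested_velocity_sampler <- function(fine, coarse, fine_bathy = NULL,
                                    coarse_bathy = NULL) {
  stopifnot(inherits(coarse, "velocity_field_set"))
  if (!is.null(fine)) {
    stopifnot(inherits(fine, "velocity_field_set"))
    if (fine$mode != coarse$mode)
      stop("fine and coarse fields must share a mode", call. = FALSE)
    fb <- grid_bounds(fine$grid); cb <- grid_bounds(coarse$grid)
    if (!(fb["xmin"] > cb["xmin"] && fb["xmax"] < cb["xmax"] &&
          fb["ymin"] > cb["ymin"] && fb["ymax"] < cb["ymax"]))
      stop("fine bounds must lie strictly inside coarse bounds", call. = FALSE)
  }
  structure(list(fine = fine, coarse = coarse,
                 fine_bathy = fine_bathy, coarse_bathy = coarse_bathy,
                 mode = coarse$mode),
            class = "nested_sampler")
}

# flatten a field (+ optional bathymetry) for the C++ core
pack_field <- function(field, bathy = NULL) {
  g <- field$grid
  list(xs = g$x, ys = g$y, zc = layer_centres(g), ts = g$times,
       u = field$u, v = field$v, w = field$w,
       mask = if (any(field$land_mask)) matrix(as.integer(field$land_mask),
                                               nrow(field$land_mask)) else NULL,
       bathy = if (!is.null(bathy)) bathy$depth else NULL)
}

pack_sampler <- function(sampler) {
  list(fine = if (!is.null(sampler$fine))
         pack_field(sampler$fine, sampler$fine_bathy) else NULL,
       coarse = pack_field(sampler$coarse, sampler$coarse_bathy),
       mode3d = sampler$mode == "full3d")
}

#' Sample a velocity at points
#'
#' Pure-R reference interpolation matching the compiled tracker core exactly;
#' used for spot checks and single-step integration. `sampler` may also be a
#' plain `function(x, y, z, t)` returning `list(u =, v =, w =)` (an analytic
#' flow), which is handy for integrator verification against closed-form
#' trajectories.
#'
#' @param sampler A `nested_sampler` or a velocity function.
#' @param x,y Positions, metres (vectorized).
#' @param z Depth below surface, metres.
#' @param t Time, hours.
#' @return List `u`, `v`, `w` (m/s) and logical `inside`; velocities are `NA`
#'   where the query is outside the coarse domain or the field time range.
#' @export
sample_velocity <- function(sampler, x, y, z = 0, t = 0) {
  if (is.function(sampler)) {
    out <- sampler(x, y, z, t)
    out$inside <- rep(TRUE, length(x))
    if (is.null(out$w)) out$w <- rep(0, length(x))
    return(out)
  }
  stopifnot(inherits(sampler, "nested_sampler"))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  z <- rep_len(z, n); t <- rep_len(t, n)
  u <- v <- w <- rep(NA_real_, n)
  inside <- rep(FALSE, n)
  for (i in seq_len(n)) {
    fld <- NULL
    if (!is.null(sampler$fine) &&
        point_in_bounds(sampler$fine$grid, x[i], y[i])) {
      fld <- sampler$fine
    } else if (point_in_bounds(sampler$coarse$grid, x[i], y[i])) {
      fld <- sampler$coarse
    }
    tr <- range(sampler$coarse$grid$times)
    if (is.null(fld) || t[i] < tr[1] - 1e-9 || t[i] > tr[2] + 1e-9) next
    inside[i] <- TRUE
    u[i] <- interp_field(fld$u, fld$grid, x[i], y[i], z[i], t[i],
                         sampler$mode == "full3d")
    v[i] <- interp_field(fld$v, fld$grid, x[i], y[i], z[i], t[i],
                         sampler$mode == "full3d")
    w[i] <- if (sampler$mode == "full3d" && !is.null(fld$w))
      interp_field(fld$w, fld$grid, x[i], y[i], z[i], t[i], TRUE) else 0
  }
  list(u = u, v = v, w = w, inside = inside)
}

point_in_bounds <- function(grid, x, y) {
  b <- grid_bounds(grid)
  x >= b["xmin"] && x <= b["xmax"] && y >= b["ymin"] && y <= b["ymax"]
}

interp_field <- function(a, grid, x, y, z, t, mode3d) {
  nx <- length(grid$x); ny <- length(grid$y)
  nl <- n_layers(grid); nt <- length(grid$times)
  dx <- if (nx > 1) (grid$x[nx] - grid$x[1]) / (nx - 1) else 1
  dy <- if (ny > 1) (grid$y[ny] - grid$y[1]) / (ny - 1) else 1
  ix <- min(max(floor((x - grid$x[1]) / dx), 0), nx - 2)
  iy <- min(max(floor((y - grid$y[1]) / dy), 0), ny - 2)
  fx <- (x - grid$x[ix + 1]) / dx
  fy <- (y - grid$y[iy + 1]) / dy
  if (nt > 1) {
    dth <- (grid$times[nt] - grid$times[1]) / (nt - 1)
    it <- min(max(floor((t - grid$times[1]) / dth), 0), nt - 2)
    ft <- (t - grid$times[it + 1]) / dth
  } else { it <- 0; ft <- 0 }
  zc <- layer_centres(grid)
  if (mode3d && nl > 1) {
    if (z <= zc[1]) { k <- 0; fz <- 0 }
    else if (z >= zc[nl]) { k <- nl - 2; fz <- 1 }
    else {
      k <- max(which(zc <= z)) - 1
      k <- min(k, nl - 2)
      fz <- (z - zc[k + 1]) / (zc[k + 2] - zc[k + 1])
    }
  } else { k <- 0; fz <- 0 }
  bil <- function(kk, tt) {
    a[ix + 1, iy + 1, kk + 1, tt + 1] * (1 - fx) * (1 - fy) +
    a[ix + 2, iy + 1, kk + 1, tt + 1] * fx * (1 - fy) +
    a[ix + 1, iy + 2, kk + 1, tt + 1] * (1 - fx) * fy +
    a[ix + 2, iy + 2, kk + 1, tt + 1] * fx * fy
  }
  lo <- bil(k, it) * (1 - ft) + (if (nt > 1) bil(k, it + 1) else bil(k, it)) * ft
  if (fz == 0) return(lo)
  hi <- bil(k + 1, it) * (1 - ft) +
        (if (nt > 1) bil(k + 1, it + 1) else bil(k + 1, it)) * ft
  lo * (1 - fz) + hi * fz
}

#' One classical Runge-Kutta (RK4) step
#'
#' Advances particle positions by one step of length `dt_min` minutes using
#' the classical 4-stage Runge-Kutta scheme on the sampled velocity field.
#' In 2D modes the depth coordinate is carried unchanged. If any stage
#' samples outside the coarse domain the particle is flagged `exited` and its
#' position left untouched.
#'
#' @param x,y,z Positions (vectorized).
#' @param t Time, hours (scalar).
#' @param sampler A `nested_sampler` or velocity function.
#' @param dt_min Step length, minutes.
#' @param mode Field mode (defaults to the sampler's).
#' @return List `x`, `y`, `z`, `exited` (logical).
#' @export
step_rk4 <- function(x, y, z, t, sampler, dt_min,
                     mode = if (is.function(sampler)) "depthavg2d" else sampler$mode) {
  dt_s <- dt_min * 60
  dt_h <- dt_min / 60
  mode3d <- mode == "full3d"
  s1 <- sample_velocity(sampler, x, y, z, t)
  s2 <- sample_velocity(sampler, x + 0.5 * dt_s * s1$u, y + 0.5 * dt_s * s1$v,
                        z + 0.5 * dt_s * s1$w * mode3d, t + 0.5 * dt_h)
  s3 <- sample_velocity(sampler, x + 0.5 * dt_s * s2$u, y + 0.5 * dt_s * s2$v,
                        z + 0.5 * dt_s * s2$w * mode3d, t + 0.5 * dt_h)
  s4 <- sample_velocity(sampler, x + dt_s * s3$u, y + dt_s * s3$v,
                        z + dt_s * s3$w * mode3d, t + dt_h)
  ok <- s1$inside & s2$inside & s3$inside & s4$inside
  nx <- x + dt_s / 6 * (s1$u + 2 * s2$u + 2 * s3$u + s4$u)
  ny <- y + dt_s / 6 * (s1$v + 2 * s2$v + 2 * s3$v + s4$v)
  nz <- if (mode3d) z + dt_s / 6 * (s1$w + 2 * s2$w + 2 * s3$w + s4$w) else z
  if (!is.function(sampler)) {
    b <- unname(grid_bounds(sampler$coarse$grid))
    ok <- ok & !is.na(nx) & !is.na(ny) &
      nx >= b[1] & nx <= b[2] & ny >= b[3] & ny <= b[4]
  }
  list(x = unname(ifelse(ok, nx, x)), y = unname(ifelse(ok, ny, y)),
       z = unname(ifelse(ok & mode3d, nz, z)), exited = unname(!ok))
}
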