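STATUS_LEVELS <- c("active", "settled", "dead", "exited")

status_code <- function(label) match(label, STATUS_LEVELS) - 1L
status_label <- function(code) STATUS_LEVELS[code + 1L]

#' Tracker configuration
#'
#' @param step_min Integrator step, minutes (default 5).
#' @param record_min Position-recording cadence, minutes (default 15); must
#'   be an integer multiple of `step_min`.
#' @param duration_days Tracking horizon, days (default 30).
#' @param mode Velocity mode, one of `"surface2d"`, `"depthavg2d"`,
#'   `"full3d"`.
#' @param start_time Simulation clock origin, hours (default 0).
#' @param seed Integer seed recorded with the run.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(step_min = 5, record_min = 15, duration_days = 30,
                           mode = c("full3d", "surface2d", "depthavg2d"),
                           start_time = 0, seed = 1L) {
  mode <- match.arg(mode)
  if (duration_days <= 0) stop("duration must be positive", call. = FALSE)
  if (record_min %% step_min != 0)
    stop("record_min must be an integer multiple of step_min", call. = FALSE)
  structure(list(step_min = step_min, record_min = record_min,
                 duration_days = duration_days, mode = mode,
                 start_time = start_time, seed = as.integer(seed)),
            class = "tracker_config")
}

#' Track particles through a nested velocity field
#'
#' Advects each particle with 5-minute (by default) RK4 steps from the first
#' global step boundary at or after its release time, records positions on
#' the 15-minute cadence, and consults the status hook at every record point.
#' Particles that sample outside the coarse (outer) domain are removed as
#' `exited`; leaving the fine domain alone is not removal, and re-entry is
#' allowed. Settled, dead and exited particles are no longer advected.
#'
#' @param particles Data frame with columns `particle_id`, `source_site`,
#'   `x`, `y`, `z`, `release_time` (hours).
#' @param sampler A [nested_velocity_sampler()].
#' @param config A [tracker_config()]; tracking covers
#'   `[start_time, start_time + duration]` and every release must fall inside
#'   it.
#' @param settlement_hook Optional `function(active_df, time_hours)` called
#'   at each record point with the active particles
#'   (`particle_id, source_site, x, y, z, age_days`); it returns `NULL` or a
#'   data frame `particle_id, status, settle_site` for particles whose status
#'   changes (`status` one of `"settled"`, `"dead"`).
#' @return An object of class `trajectories`: record `times` (hours),
#'   position matrices `x`, `y`, `z` (`n_particles x n_records`, `NA` before
#'   release and after a terminal status), the `particles` table, and final
#'   `status`, `settle_site`, `status_time` vectors.
#' @export
track <- function(particles, sampler, config, settlement_hook = NULL) {
  stopifnot(inherits(config, "tracker_config"))
  req <- c("particle_id", "source_site", "x", "y", "z", "release_time")
  if (!all(req %in% names(particles)))
    stop("particles must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  np <- nrow(particles)
  step_h <- config$step_min / 60
  t0 <- config$start_time
  n_steps <- round(config$duration_days * 24 / step_h)
  stride <- config$record_min %/% config$step_min
  n_rec <- n_steps %/% stride
  if (np > 0 && (min(particles$release_time) < t0 - 1e-9 ||
                 max(particles$release_time) > t0 + n_steps * step_h))
    stop("release times outside the simulated window", call. = FALSE)

  packed <- pack_sampler(sampler)
  mode3d <- config$mode == "full3d"
  x <- particles$x; y <- particles$y
  z <- if (mode3d) particles$z else rep(0, np)
  status <- rep(0L, np)
  released <- rep(FALSE, np)
  recorded_terminal <- rep(FALSE, np)
  settle_site <- rep(NA_integer_, np)
  status_time <- rep(NA_real_, np)
  release_step <- ceiling(round((particles$release_time - t0) / step_h, 9))

  rec_times <- t0 + seq_len(n_rec) * stride * step_h
  X <- Y <- Z <- matrix(NA_real_, np, n_rec)

  update_from_hook <- function(res, t_now) {
    if (is.null(res) || nrow(res) == 0L) return(invisible())
    idx <- match(res$particle_id, particles$particle_id)
    for (r in seq_len(nrow(res))) {
      i <- idx[r]
      if (status[i] != 0L) next
      status[i] <<- status_code(res$status[r])
      status_time[i] <<- t_now
      if (!is.null(res$settle_site) && !is.na(res$settle_site[r]))
        settle_site[i] <<- res$settle_site[r]
    }
  }

  advance <- function(idx, from_step, n) {
    if (length(idx) == 0L || n <= 0L) return(invisible())
    res <- advance_particles_cpp(x[idx], y[idx], z[idx], status[idx],
                                 t0 + from_step * step_h, as.integer(n),
                                 config$step_min * 60,
                                 packed$fine, packed$coarse, mode3d)
    x[idx] <<- res$x; y[idx] <<- res$y; z[idx] <<- res$z
    newly_exited <- idx[res$status == 3L & status[idx] == 0L]
    status[idx] <<- res$status
    status_time[newly_exited] <<- t0 + (from_step + n) * step_h
  }

  for (rec in seq_len(n_rec)) {
    k0 <- (rec - 1L) * stride
    k <- rec * stride
    # particles already in the water advance the whole interval; particles
    # released mid-interval advance their remaining steps only
    advance(which(release_step <= k0 & status == 0L), k0, stride)
    entering <- which(release_step > k0 & release_step < k & status == 0L)
    for (rs in unique(release_step[entering]))
      advance(entering[release_step[entering] == rs], rs, k - rs)
    released <- released | (release_step < k)
    {
      t_now <- t0 + k * step_h
      live <- which(released & !recorded_terminal)
      X[live, rec] <- x[live]; Y[live, rec] <- y[live]; Z[live, rec] <- z[live]
      recorded_terminal[live[status[live] != 0L]] <- TRUE
      if (!is.null(settlement_hook)) {
        act <- which(released & status == 0L)
        if (length(act)) {
          df <- quick_df(list(
            particle_id = particles$particle_id[act],
            source_site = particles$source_site[act],
            x = x[act], y = y[act], z = z[act],
            age_days = (t_now - particles$release_time[act]) / 24))
          update_from_hook(settlement_hook(df, t_now), t_now)
        }
      }
      # a particle terminal at this record keeps this record as its last
      recorded_terminal <- recorded_terminal | (released & status != 0L)
    }
  }
  structure(list(times = rec_times, x = X, y = Y, z = Z,
                 particles = particles[, req],
                 status = status, status_label = status_label(status),
                 settle_site = settle_site, status_time = status_time,
                 config = config),
            class = "trajectories")
}

#' @export
print.trajectories <- function(x, ...) {
  cat("<trajectories> ", nrow(x$particles), " particles, ",
      length(x$times), " records\n", sep = "")
  print(accounting(x))
  invisible(x)
}

#' Particle status accounting
#'
#' Tallies final particle statuses; the conservation identity
#' `released = active + settled + dead + exited` holds by construction and is
#' asserted here.
#'
#' @param trajectories A `trajectories` object.
#' @return Named integer vector `released`, `active`, `settled`, `dead`,
#'   `exited`.
#' @export
accounting <- function(trajectories) {
  counts <- vapply(STATUS_LEVELS, function(s)
    sum(trajectories$status_label == s), integer(1))
  out <- c(released = nrow(trajectories$particles), counts)
  stopifnot(out["released"] == sum(counts))
  out
}

#' Write / read trajectories as NetCDF
#'
#' Dimensions `particle` x `record_time`; variables `x`, `y`, `z` (metres),
#' final `status` (integer code), `settle_site`, `release_time` and
#' `source_site`.
#'
#' @param trajectories A `trajectories` object.
#' @param path Output file.
#' @return `path` invisibly (writer); a list mirroring the stored arrays
#'   (reader).
#' @export
write_trajectories_nc <- function(trajectories, path) {
  np <- nrow(trajectories$particles)
  dim_p <- ncdf4::ncdim_def("particle", "", seq_len(np))
  dim_t <- ncdf4::ncdim_def("record_time", "hours", trajectories$times)
  mv <- -1e30
  vx <- ncdf4::ncvar_def("x", "m", list(dim_p, dim_t), mv, prec = "double")
  vy <- ncdf4::ncvar_def("y", "m", list(dim_p, dim_t), mv, prec = "double")
  vz <- ncdf4::ncvar_def("z", "m", list(dim_p, dim_t), mv, prec = "double")
  vs <- ncdf4::ncvar_def("status", "", dim_p, -1, prec = "integer")
  vk <- ncdf4::ncvar_def("settle_site", "", dim_p, -1, prec = "integer")
  vr <- ncdf4::ncvar_def("release_time", "hours", dim_p, mv, prec = "double")
  vo <- ncdf4::ncvar_def("source_site", "", dim_p, -1, prec = "integer")
  nc <- ncdf4::nc_create(path, list(vx, vy, vz, vs, vk, vr, vo))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vx, trajectories$x)
  ncdf4::ncvar_put(nc, vy, trajectories$y)
  ncdf4::ncvar_put(nc, vz, trajectories$z)
  ncdf4::ncvar_put(nc, vs, trajectories$status)
  sk <- trajectories$settle_site; sk[is.na(sk)] <- -1L
  ncdf4::ncvar_put(nc, vk, sk)
  ncdf4::ncvar_put(nc, vr, trajectories$particles$release_time)
  ncdf4::ncvar_put(nc, vo, trajectories$particles$source_site)
  invisible(path)
}

#' @rdname write_trajectories_nc
#' @export
read_trajectories_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  np <- nc$dim$particle$len; nr <- nc$dim$record_time$len
  get_mat <- function(nm) matrix(ncdf4::ncvar_get(nc, nm,
                                                  collapse_degen = FALSE),
                                 np, nr)
  out <- list(times = as.vector(nc$dim$record_time$vals),
              x = get_mat("x"), y = get_mat("y"), z = get_mat("z"),
              status = as.vector(ncdf4::ncvar_get(nc, "status")),
              settle_site = as.vector(ncdf4::ncvar_get(nc, "settle_site")),
              release_time = as.vector(ncdf4::ncvar_get(nc, "release_time")),
              source_site = as.vector(ncdf4::ncvar_get(nc, "source_site")))
  out$settle_site[out$settle_site < 0] <- NA_integer_
  out
}

#' Write / read a velocity field set as NetCDF
#'
#' CF-style layout: dimensions `x`, `y`, `depth` (layer centres), `time`;
#' variables `u`, `v` (and `w` for 3D fields), `mask`; layer interfaces and
#' mode stored as global attributes.
#'
#' @param field A [velocity_field_set()].
#' @param path Output file.
#' @return `path` invisibly (writer); a `velocity_field_set` (reader).
#' @export
write_velocity_nc <- function(field, path) {
  g <- field$grid
  dim_x <- ncdf4::ncdim_def("x", "m", g$x)
  dim_y <- ncdf4::ncdim_def("y", "m", g$y)
  dim_z <- ncdf4::ncdim_def("depth", "m", layer_centres(g))
  dim_t <- ncdf4::ncdim_def("time", "hours", g$times)
  dims <- list(dim_x, dim_y, dim_z, dim_t)
  mv <- -1e30
  vars <- list(u = ncdf4::ncvar_def("u", "m s-1", dims, mv, prec = "double"),
               v = ncdf4::ncvar_def("v", "m s-1", dims, mv, prec = "double"),
               mask = ncdf4::ncvar_def("mask", "", list(dim_x, dim_y), -1,
                                       prec = "integer"))
  if (!is.null(field$w))
    vars$w <- ncdf4::ncvar_def("w", "m s-1", dims, mv, prec = "double")
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vars$u, field$u)
  ncdf4::ncvar_put(nc, vars$v, field$v)
  if (!is.null(field$w)) ncdf4::ncvar_put(nc, vars$w, field$w)
  ncdf4::ncvar_put(nc, vars$mask, matrix(as.integer(field$land_mask),
                                         nrow(field$land_mask)))
  ncdf4::ncatt_put(nc, 0, "layer_interfaces",
                   paste(g$layer_interfaces, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "mode", field$mode)
  invisible(path)
}

#' @rdname write_velocity_nc
#' @export
read_velocity_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  zi <- as.numeric(strsplit(ncdf4::ncatt_get(nc, 0, "layer_interfaces")$value,
                            ",")[[1]])
  mode <- ncdf4::ncatt_get(nc, 0, "mode")$value
  g <- grid_spec(nc$dim$x$vals, nc$dim$y$vals, zi, nc$dim$time$vals)
  dims <- c(length(g$x), length(g$y), n_layers(g), length(g$times))
  get_arr <- function(nm) array(ncdf4::ncvar_get(nc, nm, collapse_degen = FALSE),
                                dim = dims)
  w <- if ("w" %in% names(nc$var)) get_arr("w") else NULL
  mask <- matrix(ncdf4::ncvar_get(nc, "mask") == 1L, dims[1], dims[2])
  velocity_field_set(g, get_arr("u"), get_arr("v"), w, mode = mode,
                     land_mask = mask)
}
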