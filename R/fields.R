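#' Gridded velocity field set
#'
#' Container for hourly gridded velocities on a rectilinear grid. `u`, `v`
#' (and `w` for full-3D fields) are arrays of dimension
#' `(nx, ny, n_layers, n_times)` in m/s. 2D variants (`surface2d`,
#' `depthavg2d`) carry exactly one layer and no `w`. Velocities are exactly
#' zero on land cells.
#'
#' @param grid A [grid_spec()].
#' @param u,v,w Velocity component arrays, m/s, dim `(nx, ny, nl, nt)`.
#'   `w` is `NULL` for 2D modes (positive `w` is downward, metres below
#'   surface increasing).
#' @param mode One of `"surface2d"`, `"depthavg2d"`, `"full3d"`.
#' @param land_mask Logical `nx x ny` matrix, `TRUE` on land. Default all
#'   water.
#' @return An object of class `velocity_field_set`.
#' @export
velocity_field_set <- function(grid, u, v, w = NULL,
                               mode = c("full3d", "surface2d", "depthavg2d"),
                               land_mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid_spec"))
  nl <- n_layers(grid)
  dims <- c(length(grid$x), length(grid$y), nl, length(grid$times))
  for (nm in c("u", "v")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dims)))
      stop("'", nm, "' must have dim (nx, ny, n_layers, n_times) = (",
           paste(dims, collapse = ", "), ")", call. = FALSE)
  }
  if (mode != "full3d") {
    if (nl != 1L) stop("2D modes must have exactly one layer", call. = FALSE)
    if (!is.null(w)) stop("2D modes carry no vertical velocity", call. = FALSE)
  } else if (!is.null(w) && !identical(dim(w), as.integer(dims))) {
    stop("'w' must match the u/v dimensions", call. = FALSE)
  }
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, dims[1], dims[2])
  }
  stopifnot(identical(dim(land_mask), as.integer(dims[1:2])))
  if (anyNA(u) || anyNA(v) || (!is.null(w) && anyNA(w)))
    stop("velocity fields must be finite everywhere", call. = FALSE)
  fld <- structure(
    list(grid = grid, u = u, v = v, w = w, mode = mode,
         land_mask = land_mask),
    class = "velocity_field_set")
  mask_land(fld)
}

#' @export
print.velocity_field_set <- function(x, ...) {
  cat("<velocity_field_set> mode=", x$mode, ", ", sep = "")
  print(x$grid)
  invisible(x)
}

# zero all velocity components on land columns
mask_land <- function(field) {
  if (!any(field$land_mask)) return(field)
  idx <- which(field$land_mask)  # linear over (nx, ny)
  nxy <- prod(dim(field$u)[1:2])
  rest <- prod(dim(field$u)[3:4])
  zero_cols <- function(a) {
    m <- matrix(a, nxy, rest)
    m[idx, ] <- 0
    array(m, dim(a))
  }
  field$u <- zero_cols(field$u)
  field$v <- zero_cols(field$v)
  if (!is.null(field$w)) field$w <- zero_cols(field$w)
  field
}

#' Analytic drift-plus-tide velocity field
#'
#' Generates the canonical synthetic flow used throughout the package: a
#' steady mean drift with a superimposed sinusoidal tidal oscillation, scaled
#' per layer by a shear multiplier,
#' `u(t, layer k) = shear[k] * (mean_u + tidal_amp * sin(2*pi*t/tidal_period))`
#' (and identically for `v`); `w` is zero. The time average of `u` over whole
#' tidal periods is therefore `shear[k] * mean_u` in every layer. This
#' emulates the persistent offshore-to-onshore drift with tidal reversals that
#' reef-scale hydrodynamic models produce, without any hydrodynamics.
#'
#' @param grid A [grid_spec()].
#' @param mean_u,mean_v Mean drift components, m/s.
#' @param tidal_amp Tidal current amplitude, m/s.
#' @param tidal_period Tidal period, hours (> 0); the M2 period 12.42 h is a
#'   natural choice.
#' @param shear Per-layer velocity multipliers (length = number of layers).
#' @param phase Tidal phase offset, radians.
#' @param bathy Optional [make_reef_bathymetry()] output; cells with depth
#'   <= 0 become land with zero velocity.
#' @param mode Field mode; `"full3d"` unless the grid has one layer.
#' @param seed Unused by the deterministic generator; accepted so scenario
#'   code can pass a uniform argument set.
#' @return A [velocity_field_set()].
#' @export
make_drift_tide_field <- function(grid, mean_u = 0, mean_v = 0,
                                  tidal_amp = 0, tidal_period = 12.42,
                                  shear = rep(1, n_layers(grid)),
                                  phase = 0, bathy = NULL,
                                  mode = if (n_layers(grid) == 1L) "depthavg2d" else "full3d",
                                  seed = NULL) {
  if (tidal_period <= 0) stop("tidal_period must be > 0", call. = FALSE)
  nl <- n_layers(grid)
  if (length(shear) != nl)
    stop("'shear' needs one multiplier per layer (", nl, ")", call. = FALSE)
  nx <- length(grid$x); ny <- length(grid$y); nt <- length(grid$times)
  tide <- tidal_amp * sin(2 * pi * grid$times / tidal_period + phase)
  # outer over (layer, time): amplitude per layer/time, constant in space
  amp_u <- outer(shear, mean_u + tide)   # nl x nt
  amp_v <- outer(shear, mean_v + tide)
  u <- array(rep(amp_u, each = nx * ny), dim = c(nx, ny, nl, nt))
  v <- array(rep(amp_v, each = nx * ny), dim = c(nx, ny, nl, nt))
  w <- if (mode == "full3d") array(0, dim = c(nx, ny, nl, nt)) else NULL
  land <- if (!is.null(bathy)) bathy$depth <= 0 else NULL
  velocity_field_set(grid, u, v, w, mode = mode, land_mask = land)
}

#' Synthetic reef-platform bathymetry
#'
#' Builds a positive-down depth field with one or more shallow reef platforms
#' in a deep background: depth equals `crest_depth` inside each platform
#' radius and ramps smoothly (cubic smoothstep over one extra radius) to
#' `background_depth` outside. Overlapping platforms take the minimum depth.
#'
#' @param grid A [grid_spec()] (only x/y are used).
#' @param platforms List of `list(centre = c(x, y), radius, crest_depth)`;
#'   radii must be positive and `crest_depth < background_depth`.
#' @param background_depth Deep-water depth, metres.
#' @return An object of class `bathymetry_field` with a `depth` matrix
#'   (`nx x ny`, metres, positive down) and the generating `grid`.
#' @export
make_reef_bathymetry <- function(grid, platforms = list(),
                                 background_depth = 45) {
  nx <- length(grid$x); ny <- length(grid$y)
  depth <- matrix(background_depth, nx, ny)
  xs <- matrix(grid$x, nx, ny)
  ys <- matrix(grid$y, nx, ny, byrow = TRUE)
  for (p in platforms) {
    if (is.null(p$radius) || p$radius <= 0)
      stop("platform radius must be positive", call. = FALSE)
    if (p$crest_depth >= background_depth)
      stop("crest_depth must be shallower than background_depth", call. = FALSE)
    r <- sqrt((xs - p$centre[1])^2 + (ys - p$centre[2])^2)
    s <- pmin(pmax((r - p$radius) / p$radius, 0), 1)
    s <- s * s * (3 - 2 * s)  # smoothstep
    d <- p$crest_depth + (background_depth - p$crest_depth) * s
    depth <- pmin(depth, d)
  }
  structure(list(grid = grid, depth = depth), class = "bathymetry_field")
}

#' Extract the surface layer of a 3D field
#'
#' Returns a single-layer `surface2d` field whose velocities equal layer 1 of
#' the input bit-exactly.
#'
#' @param field3d A `full3d` [velocity_field_set()].
#' @return A `surface2d` [velocity_field_set()].
#' @export
derive_surface <- function(field3d) {
  stopifnot(inherits(field3d, "velocity_field_set"))
  if (field3d$mode != "full3d")
    stop("derive_surface() requires a full3d field", call. = FALSE)
  g <- field3d$grid
  g1 <- grid_spec(g$x, g$y, g$layer_interfaces[1:2], g$times)
  keep <- function(a) a[, , 1L, , drop = FALSE]
  velocity_field_set(g1, keep(field3d$u), keep(field3d$v), NULL,
                     mode = "surface2d", land_mask = field3d$land_mask)
}

#' Depth-average a 3D field over the local water column
#'
#' Collapses a full-3D field to a single-layer `depthavg2d` field. Each
#' horizontal velocity is the layer-thickness-weighted mean over the layers
#' above the local seabed; layer thicknesses are clipped to the local depth,
#' so a layer below the seabed contributes nothing and a partially submerged
#' layer contributes its wet fraction. Cells with no water column become land
#' with zero velocity.
#'
#' @param field3d A `full3d` [velocity_field_set()].
#' @param bathy A [make_reef_bathymetry()] field on the same grid.
#' @return A `depthavg2d` [velocity_field_set()].
#' @export
derive_depth_averaged <- function(field3d, bathy) {
  stopifnot(inherits(field3d, "velocity_field_set"),
            inherits(bathy, "bathymetry_field"))
  if (field3d$mode != "full3d")
    stop("derive_depth_averaged() requires a full3d field", call. = FALSE)
  g <- field3d$grid
  nx <- length(g$x); ny <- length(g$y); nl <- n_layers(g); nt <- length(g$times)
  if (!identical(dim(bathy$depth), c(nx, ny)))
    stop("bathymetry grid does not match the velocity grid", call. = FALSE)
  zi <- g$layer_interfaces
  D <- pmax(bathy$depth, 0)
  # wet thickness of layer k at each cell: clip [zi[k], zi[k+1]] to [0, D]
  wts <- array(0, dim = c(nx, ny, nl))
  for (k in seq_len(nl))
    wts[, , k] <- pmax(pmin(zi[k + 1], D) - zi[k], 0)
  tot <- rowSums(wts, dims = 2)
  wet <- tot > 0
  avg <- function(a) {
    out <- array(0, dim = c(nx, ny, 1L, nt))
    for (k in seq_len(nl)) {
      wk <- wts[, , k]
      out[, , 1L, ] <- out[, , 1L, ] + a[, , k, ] * as.vector(wk)
    }
    sweepden <- ifelse(wet, tot, 1)
    out[, , 1L, ] <- out[, , 1L, ] / as.vector(sweepden)
    out
  }
  g1 <- grid_spec(g$x, g$y, c(0, zi[length(zi)]), g$times)
  land <- field3d$land_mask | !wet
  velocity_field_set(g1, avg(field3d$u), avg(field3d$v), NULL,
                     mode = "depthavg2d", land_mask = land)
}
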