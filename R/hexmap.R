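#' @useDynLib reefdrift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif setNames cor
#' @importFrom utils head read.csv write.csv
NULL

HABITAT_ZONES <- c("ReefSlope", "ReefCrest", "ShelteredSlope", "OuterReefFlat")

# pointy-top hexagon lattice: axial (q, r) -> centre (x, y), circumradius s
hex_axial_to_xy <- function(q, r, size, centre = c(0, 0)) {
  list(x = centre[1] + size * sqrt(3) * (q + r / 2),
       y = centre[2] + size * 1.5 * r)
}

# inverse: (x, y) -> nearest axial cell (cube rounding)
hex_xy_to_axial <- function(x, y, size, centre = c(0, 0)) {
  x <- (x - centre[1]); y <- (y - centre[2])
  qf <- (sqrt(3) / 3 * x - y / 3) / size
  rf <- (2 / 3 * y) / size
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fixq <- dq > dr & dq > ds
  fixr <- !fixq & dr > ds
  q[fixq] <- -r[fixq] - s[fixq]
  r[fixr] <- -q[fixr] - s[fixr]
  list(q = as.integer(q), r = as.integer(r))
}

hex_ring_distance <- function(q, r) (abs(q) + abs(r) + abs(q + r)) / 2

#' Hexagon vertex rings
#'
#' Vertex coordinates of one pointy-top hexagon (closed ring, 7 points).
#'
#' @param cx,cy Hexagon centre.
#' @param size Circumradius (metres).
#' @return A two-column matrix of x/y vertex coordinates.
#' @export
hex_vertex_ring <- function(cx, cy, size) {
  a <- pi / 180 * (60 * 0:5 + 30)
  cbind(x = cx + size * cos(c(a, a[1])), y = cy + size * sin(c(a, a[1])))
}

#' Synthetic hexagonal habitat map
#'
#' Generates a hexagonal lattice of `1 + 3*n_rings*(n_rings+1)` equal-area
#' hexagons around a centre, each assigned one of the four geomorphic habitat
#' zones (Reef Slope, Reef Crest, Sheltered Slope, Outer Reef Flat) and a
#' depth. The default zone rule emulates a reef platform: an interior reef
#' flat, a shallow crest ring one ring in from the edge, and an outer ring
#' split into an exposed (east) Reef Slope and a Sheltered (west) Slope — so
#' the two slope zones each form patches that are not contiguous with one
#' another. The default depth rule is monotone in ring distance from the
#' crest, with optional seeded metre-scale noise.
#'
#' @param n_rings Number of rings around the central hexagon (>= 1).
#' @param hex_area Area of each hexagon, m^2.
#' @param zone_rule `function(ring, n_rings, x, y)` returning a zone name per
#'   hexagon (vectorized); `NULL` for the default platform rule.
#' @param depth_rule `function(ring, n_rings)` returning depth (m, positive
#'   down) per hexagon; `NULL` for the default monotone rule.
#' @param centre_axial Integer axial (q, r) offset of the map centre on the
#'   global lattice; maps generated with the same `hex_area` and different
#'   `centre_axial` share one lattice and can be combined with
#'   [bind_hexagon_maps()].
#' @param depth_noise_sd Std. dev. (m) of seeded depth noise; 0 disables.
#' @param id_offset Added to hexagon ids (for combining maps).
#' @param seed Integer seed for the depth noise.
#' @return An object of class `hexagon_map`: a data frame of hexagons
#'   (`id, q, r, x, y, ring, zone, depth`) plus lattice metadata
#'   (`size`, `hex_area`).
#' @export
make_hexagon_map <- function(n_rings, hex_area = 62500 / 4,
                             zone_rule = NULL, depth_rule = NULL,
                             centre_axial = c(0L, 0L),
                             depth_noise_sd = 0, id_offset = 0L,
                             seed = 1L) {
  stopifnot(n_rings >= 1, hex_area > 0)
  size <- sqrt(hex_area * 2 / (3 * sqrt(3)))
  qs <- integer(0); rs <- integer(0)
  for (q in -n_rings:n_rings) {
    rr <- max(-n_rings, -q - n_rings):min(n_rings, -q + n_rings)
    qs <- c(qs, rep.int(q, length(rr))); rs <- c(rs, rr)
  }
  ring <- hex_ring_distance(qs, rs)
  gq <- qs + centre_axial[1]; gr <- rs + centre_axial[2]
  xy <- hex_axial_to_xy(gq, gr, size)
  if (is.null(zone_rule)) zone_rule <- default_zone_rule
  if (is.null(depth_rule)) depth_rule <- default_depth_rule
  cx <- mean(xy$x); cy <- mean(xy$y)
  zone <- zone_rule(ring, n_rings, xy$x - cx, xy$y - cy)
  if (!all(zone %in% HABITAT_ZONES))
    stop("zone_rule produced values outside the four habitat zones", call. = FALSE)
  depth <- depth_rule(ring, n_rings)
  if (depth_noise_sd > 0) {
    depth <- depth + with_local_seed(seed, rnorm(length(depth), 0, depth_noise_sd))
    depth <- pmax(depth, 0.2)
  }
  hexes <- data.frame(
    id = seq_along(qs) + as.integer(id_offset),
    q = gq, r = gr, x = xy$x, y = xy$y, ring = ring,
    zone = zone, depth = depth, stringsAsFactors = FALSE)
  structure(list(hexes = hexes, size = size, hex_area = hex_area),
            class = "hexagon_map")
}

default_zone_rule <- function(ring, n_rings, x, y) {
  crest <- max(n_rings - 1L, 1L)
  zone <- rep("OuterReefFlat", length(ring))
  zone[ring == crest] <- "ReefCrest"
  outer <- ring > crest
  zone[outer & x >= 0] <- "ReefSlope"
  zone[outer & x < 0] <- "ShelteredSlope"
  zone
}

default_depth_rule <- function(ring, n_rings) {
  crest <- max(n_rings - 1L, 1L)
  1 + 1.5 * abs(ring - crest) + ifelse(ring > crest, 2.5, 0)
}

#' @export
print.hexagon_map <- function(x, ...) {
  cat("<hexagon_map> ", nrow(x$hexes), " hexagons of ",
      signif(x$hex_area, 4), " m^2 (circumradius ", signif(x$size, 4),
      " m)\n", sep = "")
  print(table(x$hexes$zone))
  invisible(x)
}

#' Combine hexagon maps that share one lattice
#'
#' @param ... `hexagon_map` objects with equal `hex_area`, generated with
#'   different `centre_axial` offsets; hexagon ids and axial cells must not
#'   collide.
#' @return A single `hexagon_map`.
#' @export
bind_hexagon_maps <- function(...) {
  maps <- list(...)
  stopifnot(length(maps) >= 1)
  size <- maps[[1]]$size
  for (m in maps)
    if (abs(m$size - size) > 1e-9)
      stop("maps must share one hexagon size to be combined", call. = FALSE)
  hexes <- do.call(rbind, lapply(maps, `[[`, "hexes"))
  if (anyDuplicated(hexes$id))
    stop("hexagon ids collide; use id_offset", call. = FALSE)
  if (anyDuplicated(hexes[, c("q", "r")]))
    stop("maps overlap on the lattice", call. = FALSE)
  structure(list(hexes = hexes, size = size, hex_area = maps[[1]]$hex_area),
            class = "hexagon_map")
}

#' Locate the hexagon containing a point
#'
#' Maps points to hexagon ids by inverting the lattice transform (cube
#' rounding), so containment is exact up to the deterministic assignment of
#' boundary points to their nearest centre.
#'
#' @param map A `hexagon_map`.
#' @param x,y Point coordinates (vectorized).
#' @return Integer hexagon ids, `NA` where the point falls outside the map.
#' @export
locate_hex <- function(map, x, y) {
  ax <- hex_xy_to_axial(x, y, map$size)
  key <- paste(ax$q, ax$r)
  map_key <- paste(map$hexes$q, map$hexes$r)
  map$hexes$id[match(key, map_key)]
}

#' Write / read a hexagon map as GeoJSON
#'
#' One Feature per hexagon (closed polygon ring; properties `id`, `zone`,
#' `depth`, `area`). Coordinates are the planar metric coordinates of the
#' scenario, recorded as-is.
#'
#' @param map A `hexagon_map`.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `hexagon_map` (reader — lattice
#'   metadata is reconstructed from the stored properties).
#' @export
write_hexmap_geojson <- function(map, path) {
  h <- map$hexes
  feats <- lapply(seq_len(nrow(h)), function(i) {
    ring <- hex_vertex_ring(h$x[i], h$y[i], map$size)
    list(type = "Feature",
         properties = list(id = h$id[i], q = h$q[i], r = h$r[i],
                           zone = h$zone[i], depth = h$depth[i],
                           area = map$hex_area),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) unname(ring[j, ])))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hexmap_geojson
#' @export
read_hexmap_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  props <- lapply(fc$features, `[[`, "properties")
  hexes <- data.frame(
    id = vapply(props, function(p) as.integer(p$id), integer(1)),
    q = vapply(props, function(p) as.integer(p$q), integer(1)),
    r = vapply(props, function(p) as.integer(p$r), integer(1)),
    zone = vapply(props, function(p) p$zone, character(1)),
    depth = vapply(props, function(p) as.numeric(p$depth), numeric(1)),
    stringsAsFactors = FALSE)
  hex_area <- as.numeric(props[[1]]$area)
  size <- sqrt(hex_area * 2 / (3 * sqrt(3)))
  xy <- hex_axial_to_xy(hexes$q, hexes$r, size)
  hexes$x <- xy$x; hexes$y <- xy$y
  hexes$ring <- hex_ring_distance(hexes$q, hexes$r)
  hexes <- hexes[, c("id", "q", "r", "x", "y", "ring", "zone", "depth")]
  structure(list(hexes = hexes, size = size, hex_area = hex_area),
            class = "hexagon_map")
}

# run expr under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# minimal-overhead data.frame for hot paths (no name mangling, no checks)
quick_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = .set_row_names(length(lst[[1]])))
}

# deterministic integer seed mixing, kept below 2^31
mix_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.numeric(p)
  }))
  h <- 17
  for (p in parts) h <- (h * 31 + (p %% 1000003)) %% 2147483629
  as.integer(h)
}
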