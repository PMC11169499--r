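#' Zone adjacency graph from Delaunay triangulation
#'
#' Builds the weighted adjacency graph over one habitat zone's hexagons.
#' Nodes are the zone's hexagons; edges are the Delaunay edges of their
#' centroids, so the graph is connected even when the zone's patches are
#' spatially non-contiguous (nearest-neighbour adjacency would fragment it).
#' Each edge carries the raw centroid distance `v_raw` (metres); call
#' [compute_edge_weights()] to attach normalized lengths and weights.
#'
#' @param map A `hexagon_map`.
#' @param zone One of the four habitat zone names.
#' @return An object of class `hex_graph`: `nodes` (id, x, y, depth) and
#'   `edges` (i, j, v_raw) where i/j are hexagon ids with i < j.
#' @export
build_adjacency <- function(map, zone) {
  stopifnot(zone %in% HABITAT_ZONES)
  h <- map$hexes[map$hexes$zone == zone, , drop = FALSE]
  if (nrow(h) == 0L) stop("no hexagons in zone '", zone, "'", call. = FALSE)
  if (anyDuplicated(h[, c("x", "y")]))
    stop("duplicate hexagon centroids", call. = FALSE)
  nodes <- data.frame(id = h$id, x = h$x, y = h$y, depth = h$depth,
                      stringsAsFactors = FALSE)
  if (nrow(h) == 1L) {
    edges <- data.frame(i = integer(0), j = integer(0), v_raw = numeric(0))
  } else if (nrow(h) == 2L) {
    edges <- data.frame(i = min(h$id), j = max(h$id),
                        v_raw = sqrt(diff(h$x)^2 + diff(h$y)^2))
  } else {
    tri <- delaunay_triangulate(h$x, h$y)
    e <- tri$edges
    edges <- data.frame(
      i = pmin(h$id[e[, 1]], h$id[e[, 2]]),
      j = pmax(h$id[e[, 1]], h$id[e[, 2]]),
      v_raw = sqrt((h$x[e[, 1]] - h$x[e[, 2]])^2 +
                   (h$y[e[, 1]] - h$y[e[, 2]])^2))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, zone = zone),
            class = "hex_graph")
}

#' Edge weight from normalized length and depth difference
#'
#' The regionalization weight `w = sqrt(v_norm^2 + (d_i - d_j)^2)`: the
#' Euclidean combination of the normalized edge length and the depth
#' difference between the two hexagons. Symmetric in i/j, non-negative, and
#' zero exactly when the normalized length is zero and the depths are equal.
#'
#' @param v_norm Normalized edge length(s), >= 0 (dimensionless).
#' @param d_i,d_j Hexagon depths, metres.
#' @return Weight(s), dimensionless.
#' @export
edge_weight <- function(v_norm, d_i, d_j) {
  if (any(v_norm < 0)) stop("v_norm must be >= 0", call. = FALSE)
  sqrt(v_norm^2 + (d_i - d_j)^2)
}

#' Attach normalized lengths and weights to a hex graph
#'
#' Normalizes each edge's centroid distance by the maximum distance in the
#' graph (so `v_norm` is in (0, 1]) and computes [edge_weight()] using the
#' endpoint depths; depth differences stay in metres.
#'
#' @param graph A `hex_graph` from [build_adjacency()].
#' @return The graph with `v_norm` and `w` columns added to `edges`.
#' @export
compute_edge_weights <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) {
    e$v_norm <- numeric(0); e$w <- numeric(0)
    graph$edges <- e
    return(graph)
  }
  d <- setNames(graph$nodes$depth, graph$nodes$id)
  e$v_norm <- e$v_raw / max(e$v_raw)
  e$w <- edge_weight(e$v_norm, d[as.character(e$i)], d[as.character(e$j)])
  graph$edges <- e
  graph
}

#' Minimum spanning tree of a weighted hex graph
#'
#' Kruskal's algorithm; ties are broken by (weight, smaller id pair) in
#' lexicographic order, making the tree deterministic even on lattices where
#' many edges share the same weight.
#'
#' @param graph A `hex_graph` with weights (see [compute_edge_weights()]).
#' @return An object of class `spanning_tree` with `edges` (subset of the
#'   graph's edge rows) and `nodes`.
#' @export
minimum_spanning_tree <- function(graph) {
  e <- graph$edges
  if (is.null(e$w)) stop("compute_edge_weights() first", call. = FALSE)
  ids <- graph$nodes$id
  parent <- seq_along(ids)
  names(parent) <- ids
  find <- function(a) {
    root <- a
    while (parent[root] != root) root <- parent[root]
    root
  }
  picked <- logical(nrow(e))
  if (nrow(e) > 0L) {
    ord <- order(e$w, pmin(e$i, e$j), pmax(e$i, e$j))
    idx <- match(as.character(c(e$i, e$j)), as.character(ids))
    ii <- idx[seq_len(nrow(e))]; jj <- idx[-seq_len(nrow(e))]
    for (k in ord) {
      ra <- find(ii[k]); rb <- find(jj[k])
      if (ra != rb) {
        parent[ra] <- rb
        picked[k] <- TRUE
      }
    }
  }
  structure(list(nodes = graph$nodes,
                 edges = e[picked, , drop = FALSE],
                 zone = graph$zone),
            class = "spanning_tree")
}

# adjacency list over tree edges, indexed by position in `ids`
tree_adjacency <- function(ids, edges) {
  adj <- vector("list", length(ids))
  ii <- match(edges$i, ids); jj <- match(edges$j, ids)
  for (k in seq_along(ii)) {
    adj[[ii[k]]] <- c(adj[[ii[k]]], list(c(jj[k], k)))
    adj[[jj[k]]] <- c(adj[[jj[k]]], list(c(ii[k], k)))
  }
  adj
}

tree_components <- function(ids, edges) {
  adj <- tree_adjacency(ids, edges)
  comp <- rep(NA_integer_, length(ids))
  cid <- 0L
  for (s in seq_along(ids)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      for (nb in adj[[v]]) if (is.na(comp[nb[1]])) stack <- c(stack, nb[1])
    }
  }
  comp
}

#' Partition a spanning tree into site polygons
#'
#' Splits the minimum spanning tree into contiguous clusters of hexagons by
#' iterative best-edge removal: at each step, delete the tree edge whose
#' removal most reduces the within-cluster depth heterogeneity (sum of squared
#' deviations of hexagon depth), subject to both resulting components holding
#' at least `min_size` hexagons. Splitting stops when no edge can be deleted
#' without violating the minimum, or when the mean cluster area has reached
#' `target_area`. A zone component smaller than `min_size` stays one site.
#' The number of clusters is therefore not fixed in advance.
#'
#' @param tree A `spanning_tree`.
#' @param graph The `hex_graph` the tree came from (supplies depths).
#' @param min_size Minimum hexagons per site (default 200).
#' @param target_area Target site area, m^2 (default 62500).
#' @param hex_area Area of one hexagon, m^2.
#' @return Integer cluster labels named by hexagon id.
#' @export
partition_tree <- function(tree, graph, min_size = 200,
                           target_area = 62500, hex_area) {
  stopifnot(min_size >= 1, hex_area > 0)
  ids <- tree$nodes$id
  depth <- tree$nodes$depth
  n <- length(ids)
  edges <- tree$edges
  alive <- rep(TRUE, nrow(edges))

  comp_of <- function() tree_components(ids, edges[alive, , drop = FALSE])

  repeat {
    comp <- comp_of()
    sizes <- tabulate(comp)
    if (mean(sizes) * hex_area <= target_area) break
    # score every deletable edge in one rooted pass per component
    best <- NULL  # list(edge_row, reduction)
    adj <- tree_adjacency(ids, edges[alive, , drop = FALSE])
    alive_rows <- which(alive)
    for (cc in seq_along(sizes)) {
      members <- which(comp == cc)
      if (length(members) < 2 * min_size) next
      root <- members[1]
      # iterative post-order: subtree size / depth sums below each edge
      order_v <- integer(0); parent_edge <- rep(NA_integer_, n)
      parent_of <- rep(NA_integer_, n)
      stack <- root; seen <- rep(FALSE, n); seen[root] <- TRUE
      while (length(stack)) {
        v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        order_v <- c(order_v, v)
        for (nb in adj[[v]]) {
          if (!seen[nb[1]]) {
            seen[nb[1]] <- TRUE
            parent_of[nb[1]] <- v
            parent_edge[nb[1]] <- nb[2]  # index into alive rows
            stack <- c(stack, nb[1])
          }
        }
      }
      sub_n <- rep(1, n); sub_s <- depth; sub_q <- depth^2
      for (v in rev(order_v)) {
        p <- parent_of[v]
        if (!is.na(p)) {
          sub_n[p] <- sub_n[p] + sub_n[v]
          sub_s[p] <- sub_s[p] + sub_s[v]
          sub_q[p] <- sub_q[p] + sub_q[v]
        }
      }
      tot_n <- sub_n[root]; tot_s <- sub_s[root]; tot_q <- sub_q[root]
      sse <- function(nn, ss, qq) qq - ss^2 / nn
      sse_all <- sse(tot_n, tot_s, tot_q)
      for (v in order_v) {
        ek <- parent_edge[v]
        if (is.na(ek)) next
        na_ <- sub_n[v]; nb_ <- tot_n - na_
        if (na_ < min_size || nb_ < min_size) next
        red <- sse_all - sse(na_, sub_s[v], sub_q[v]) -
               sse(nb_, tot_s - sub_s[v], tot_q - sub_q[v])
        row <- alive_rows[ek]
        if (is.null(best) || red > best$red + 1e-12 ||
            (abs(red - best$red) <= 1e-12 &&
             (edges$i[row] < edges$i[best$row] ||
              (edges$i[row] == edges$i[best$row] &&
               edges$j[row] < edges$j[best$row])))) {
          best <- list(row = row, red = red)
        }
      }
    }
    if (is.null(best)) break
    alive[best$row] <- FALSE
  }
  comp <- comp_of()
  setNames(comp, ids)
}

#' Regionalize a hexagon map into site polygons
#'
#' Runs the full regionalization — per-zone Delaunay adjacency, edge
#' weighting, minimum spanning tree and size-constrained tree partition — and
#' assembles the resulting clusters into reef site polygons. Zones are
#' processed independently, so no site ever mixes habitat zones.
#'
#' @param map A `hexagon_map`.
#' @param min_size Minimum hexagons per site.
#' @param target_area Target site area, m^2.
#' @param zones Zones to process (default: every zone present in the map).
#' @return An object of class `site_set`: `sites` data frame (`site_id`,
#'   `zone`, `n_hexagons`, `area`, `centroid_x`, `centroid_y`), a `members`
#'   list of hexagon-id vectors, and the source `map`.
#' @export
make_site_polygons <- function(map, min_size = 200, target_area = 62500,
                               zones = NULL) {
  if (is.null(zones)) zones <- intersect(HABITAT_ZONES, unique(map$hexes$zone))
  sites <- list(); members <- list(); site_id <- 0L
  for (z in zones) {
    g <- compute_edge_weights(build_adjacency(map, z))
    tr <- minimum_spanning_tree(g)
    cl <- partition_tree(tr, g, min_size = min_size,
                         target_area = target_area, hex_area = map$hex_area)
    for (cc in sort(unique(cl))) {
      site_id <- site_id + 1L
      ids <- as.integer(names(cl)[cl == cc])
      hx <- map$hexes[match(ids, map$hexes$id), ]
      sites[[site_id]] <- data.frame(
        site_id = site_id, zone = z, n_hexagons = length(ids),
        area = length(ids) * map$hex_area,
        centroid_x = mean(hx$x), centroid_y = mean(hx$y),
        stringsAsFactors = FALSE)
      members[[site_id]] <- ids
    }
  }
  new_site_set(do.call(rbind, sites), members, map)
}

# site_set constructor; precomputes the axial-cell -> site-id lookup used by
# locate_site() so point queries stay cheap inside tracking hooks
new_site_set <- function(sites, members, map) {
  lut <- rep(NA_integer_, nrow(map$hexes))
  names(lut) <- paste(map$hexes$q, map$hexes$r)
  for (s in seq_along(members)) {
    i <- match(members[[s]], map$hexes$id)
    lut[i] <- sites$site_id[s]
  }
  structure(list(sites = sites, members = members, map = map, lut = lut),
            class = "site_set")
}

#' @export
print.site_set <- function(x, ...) {
  cat("<site_set> ", nrow(x$sites), " sites over ",
      sum(x$sites$n_hexagons), " hexagons\n", sep = "")
  print(x$sites)
  invisible(x)
}

#' Site-id lookup for points
#'
#' @param sites A `site_set`.
#' @param x,y Point coordinates (vectorized).
#' @return Integer site ids (`NA` outside all sites).
#' @export
locate_site <- function(sites, x, y) {
  if (is.null(sites$lut))
    sites <- new_site_set(sites$sites, sites$members, sites$map)
  ax <- hex_xy_to_axial(x, y, sites$map$size)
  unname(sites$lut[paste(ax$q, ax$r)])
}

#' Merged boundary geometry of site polygons
#'
#' Unions each site's member hexagon rings by cancelling shared internal
#' edges and chaining the remaining boundary segments into closed rings.
#' Spatially disjoint clusters (possible because tree connectivity is graph
#' connectivity, not spatial adjacency) yield multiple rings; an enclosed
#' hole also appears as its own ring.
#'
#' @param sites A `site_set`.
#' @return A named list (by site id) of lists of closed rings (two-column
#'   coordinate matrices). Total enclosed area equals
#'   `n_hexagons * hex_area` per site.
#' @export
polygons_to_geometry <- function(sites) {
  map <- sites$map
  out <- vector("list", length(sites$members))
  names(out) <- sites$sites$site_id
  for (s in seq_along(sites$members)) {
    ids <- sites$members[[s]]
    if (length(ids) == 0L) stop("empty site", call. = FALSE)
    hx <- map$hexes[match(ids, map$hexes$id), ]
    segs <- list()
    for (i in seq_len(nrow(hx))) {
      ring <- hex_vertex_ring(hx$x[i], hx$y[i], map$size)
      for (j in 1:6)
        segs[[length(segs) + 1L]] <- rbind(ring[j, ], ring[j + 1, ])
    }
    keyf <- function(p) paste(round(p[1], 3), round(p[2], 3))
    seg_keys <- vapply(segs, function(s2)
      paste(sort(c(keyf(s2[1, ]), keyf(s2[2, ]))), collapse = "|"),
      character(1))
    boundary <- segs[seg_keys %in% names(which(table(seg_keys) == 1L))]
    # chain boundary segments into rings
    rings <- list()
    used <- rep(FALSE, length(boundary))
    starts <- vapply(boundary, function(s2) keyf(s2[1, ]), character(1))
    while (any(!used)) {
      k <- which(!used)[1]
      used[k] <- TRUE
      ring <- boundary[[k]]
      repeat {
        endk <- keyf(ring[nrow(ring), ])
        nxt <- which(!used & starts == endk)
        if (length(nxt) == 0L) {
          # try reversed segments
          ends <- vapply(boundary, function(s2) keyf(s2[2, ]), character(1))
          nxt <- which(!used & ends == endk)
          if (length(nxt) == 0L) break
          used[nxt[1]] <- TRUE
          ring <- rbind(ring, boundary[[nxt[1]]][1, ])
        } else {
          used[nxt[1]] <- TRUE
          ring <- rbind(ring, boundary[[nxt[1]]][2, ])
        }
        if (keyf(ring[nrow(ring), ]) == keyf(ring[1, ])) break
      }
      rings[[length(rings) + 1L]] <- unname(ring)
    }
    out[[s]] <- rings
  }
  out
}

# absolute shoelace area of one closed ring
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Write site polygons as GeoJSON and a site table as CSV
#'
#' @param sites A `site_set`.
#' @param geojson_path,csv_path Output paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_sites <- function(sites, geojson_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path))
    write.csv(sites$sites, csv_path, row.names = FALSE)
  if (!is.null(geojson_path)) {
    geom <- polygons_to_geometry(sites)
    feats <- lapply(seq_len(nrow(sites$sites)), function(s) {
      rings <- geom[[s]]
      list(type = "Feature",
           properties = list(site_id = sites$sites$site_id[s],
                             zone = sites$sites$zone[s],
                             area = sites$sites$area[s],
                             n_hexagons = sites$sites$n_hexagons[s]),
           geometry = list(
             type = "MultiPolygon",
             coordinates = lapply(rings, function(r)
               list(lapply(seq_len(nrow(r)), function(i) unname(r[i, ]))))))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(geojson_path, csv_path))
}
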