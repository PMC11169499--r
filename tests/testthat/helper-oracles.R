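# Independent oracles and small builders shared across test files.

# exhaustive minimum-spanning-tree weight by enumerating all (n-1)-edge
# subsets; only usable for small graphs
mst_weight_by_enumeration <- function(node_ids, edges) {
  n <- length(node_ids)
  if (n <= 1 || nrow(edges) < n - 1) return(NA_real_)
  best <- Inf
  combos <- utils::combn(nrow(edges), n - 1)
  for (c_i in seq_len(ncol(combos))) {
    sel <- combos[, c_i]
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    acyclic <- TRUE
    for (k in sel) {
      ra <- find(match(edges$i[k], node_ids))
      rb <- find(match(edges$j[k], node_ids))
      if (ra == rb) { acyclic <- FALSE; break }
      parent[ra] <- rb
    }
    if (acyclic) best <- min(best, sum(edges$w[sel]))
  }
  best
}

# random connected weighted graph in hex_graph form, <= 7 nodes
random_hex_graph <- function(seed) {
  set.seed(seed)
  n <- sample(4:7, 1)
  repeat {
    pairs <- utils::combn(n, 2)
    keep <- runif(ncol(pairs)) < 0.6
    if (sum(keep) < n - 1) next
    e <- pairs[, keep, drop = FALSE]
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (k in seq_len(ncol(e))) {
      ra <- find(e[1, k]); rb <- find(e[2, k])
      if (ra != rb) parent[ra] <- rb
    }
    if (length(unique(vapply(seq_len(n), find, integer(1)))) == 1) break
  }
  nodes <- data.frame(id = seq_len(n), x = runif(n), y = runif(n),
                      depth = runif(n, 1, 10))
  edges <- data.frame(i = e[1, ], j = e[2, ],
                      v_raw = runif(ncol(e), 0.1, 5))
  g <- structure(list(nodes = nodes, edges = edges, zone = "ReefSlope"),
                 class = "hex_graph")
  compute_edge_weights(g)
}

# analytic solid-body rotation sampler (period_h hours per revolution)
rotation_sampler <- function(period_h) {
  omega <- 2 * pi / (period_h * 3600)
  function(x, y, z, t) list(u = -omega * y, v = omega * x,
                            w = rep(0, length(x)))
}

# site set of n single-hexagon sites carved from one lattice
single_hex_sites <- function(n, hex_area = 26000) {
  rings <- 1L
  while (1 + 3 * rings * (rings + 1) < n) rings <- rings + 1L
  map <- make_hexagon_map(rings, hex_area)
  map$hexes <- map$hexes[seq_len(n), , drop = FALSE]
  sites <- data.frame(site_id = seq_len(n), zone = map$hexes$zone,
                      n_hexagons = 1L, area = hex_area,
                      centroid_x = map$hexes$x, centroid_y = map$hexes$y)
  reefdrift:::new_site_set(sites, as.list(map$hexes$id), map)
}

# small uniform-flow field pair (fine nested in coarse) for tracker tests;
# velocity may vary linearly in y so bilinear sampling stays exact
uniform_flow_fields <- function(u0 = 0.1, v0 = 0, du_dy = 0,
                                n_hours = 48, one_layer = TRUE) {
  zi <- if (one_layer) c(0, 10) else c(0, 2, 10)
  mk <- function(xs, ys) {
    g <- grid_spec(xs, ys, zi, seq(0, n_hours))
    nl <- length(zi) - 1
    dims <- c(length(xs), length(ys), nl, n_hours + 1)
    uarr <- array(rep(u0 + du_dy * rep(ys, each = length(xs)),
                      times = nl * (n_hours + 1)), dims)
    varr <- array(v0, dims)
    mode <- if (one_layer) "depthavg2d" else "full3d"
    w <- if (one_layer) NULL else array(0, dims)
    velocity_field_set(g, uarr, varr, w, mode = mode)
  }
  fine <- mk(seq(-2000, 2000, 500), seq(-2000, 2000, 500))
  coarse <- mk(seq(-10000, 10000, 1000), seq(-10000, 10000, 1000))
  list(fine = fine, coarse = coarse,
       nested = nested_velocity_sampler(fine, coarse),
       coarse_only = nested_velocity_sampler(NULL, coarse))
}
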