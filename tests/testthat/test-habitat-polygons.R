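test_that("zone adjacency graphs are Delaunay-based and connected", {
  m <- make_hexagon_map(3, 1000)
  # 3 non-collinear points -> triangle
  tri <- delaunay_triangulate(c(0, 1, 0), c(0, 0, 1))
  expect_equal(nrow(tri$edges), 3)
  expect_equal(nrow(tri$triangles), 1)

  crest <- build_adjacency(m, "ReefCrest")
  expect_true(all(crest$edges$i < crest$edges$j))
  expect_true(all(c(crest$edges$i, crest$edges$j) %in% crest$nodes$id))

  # two hexagons fall back to a single edge
  m2 <- m; m2$hexes <- m$hexes[1:2, ]; m2$hexes$zone <- "ReefSlope"
  g2 <- build_adjacency(m2, "ReefSlope")
  expect_equal(nrow(g2$edges), 1)

  # duplicate centroids are rejected
  m3 <- m; m3$hexes$x[2] <- m3$hexes$x[1]; m3$hexes$y[2] <- m3$hexes$y[1]
  m3$hexes$zone[1:2] <- "ReefCrest"
  expect_error(build_adjacency(m3, "ReefCrest"), "duplicate")
})

test_that("triangulation bridges far-apart clusters into one component", {
  set.seed(42)
  for (rep in 1:5) {
    x <- c(runif(3, 0, 1), runif(3, 100, 101))
    y <- c(runif(3, 0, 1), runif(3, 0, 1))
    tri <- delaunay_triangulate(x, y)
    g <- igraph::graph_from_edgelist(tri$edges, directed = FALSE)
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("every Delaunay triangle has an empty circumcircle", {
  set.seed(7)
  x <- runif(40); y <- runif(40)
  tri <- delaunay_triangulate(x, y)
  circum <- function(i, j, k) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  for (t_i in seq_len(nrow(tri$triangles))) {
    tr <- tri$triangles[t_i, ]
    cc <- circum(tr[1], tr[2], tr[3])
    d <- sqrt((x - cc[1])^2 + (y - cc[2])^2)
    inside <- which(d < cc[3] - 1e-9)
    expect_true(all(inside %in% tr))
  }
})

test_that("edge weight is the Euclidean combination of length and depth gap", {
  expect_equal(edge_weight(0, 5, 5), 0)
  expect_equal(edge_weight(3, 10, 6), 5)     # 3-4-5 triple
  expect_equal(edge_weight(1, 2, 2), 1)
  expect_equal(edge_weight(0.7, 3, 8), edge_weight(0.7, 8, 3))  # symmetric
  expect_error(edge_weight(-1, 0, 0), "v_norm")
  # zero exactly when both terms vanish
  expect_true(edge_weight(1e-3, 1, 1) > 0)
  expect_true(edge_weight(0, 1, 1.001) > 0)
})

test_that("normalized lengths lie in (0, 1] and weights use metres of depth", {
  g <- compute_edge_weights(build_adjacency(make_hexagon_map(3, 1000),
                                            "OuterReefFlat"))
  expect_true(all(g$edges$v_norm > 0 & g$edges$v_norm <= 1))
  expect_equal(max(g$edges$v_norm), 1)
  d <- setNames(g$nodes$depth, g$nodes$id)
  expect_equal(g$edges$w,
               sqrt(g$edges$v_norm^2 +
                    (d[as.character(g$edges$i)] -
                     d[as.character(g$edges$j)])^2),
               ignore_attr = TRUE)
})

test_that("Kruskal MST matches exhaustive enumeration and igraph", {
  # fixed small cases
  tri_g <- structure(list(
    nodes = data.frame(id = 1:3, x = 0, y = 0:2, depth = 1),
    edges = data.frame(i = c(1, 2, 1), j = c(2, 3, 3), v_raw = 1,
                       v_norm = 1, w = c(1, 2, 3))), class = "hex_graph")
  tr <- minimum_spanning_tree(tri_g)
  expect_setequal(tr$edges$w, c(1, 2))

  for (seed in 1:25) {
    g <- random_hex_graph(seed)
    tr <- minimum_spanning_tree(g)
    expect_equal(nrow(tr$edges), nrow(g$nodes) - 1)
    oracle <- mst_weight_by_enumeration(g$nodes$id, g$edges)
    expect_equal(sum(tr$edges$w), oracle, tolerance = 1e-12)
    ig <- igraph::graph_from_data_frame(
      data.frame(from = g$edges$i, to = g$edges$j, weight = g$edges$w),
      directed = FALSE)
    expect_equal(sum(tr$edges$w),
                 sum(igraph::E(igraph::mst(ig))$weight), tolerance = 1e-12)
  }
})

test_that("MST tie-breaking is deterministic on equal weights", {
  g <- structure(list(
    nodes = data.frame(id = 1:4, x = 0, y = 0, depth = 1),
    edges = data.frame(i = c(1, 1, 2, 3), j = c(2, 3, 4, 4),
                       v_raw = 1, v_norm = 1, w = 1)), class = "hex_graph")
  t1 <- minimum_spanning_tree(g)
  t2 <- minimum_spanning_tree(g)
  expect_identical(t1$edges, t2$edges)
  # lexicographically smallest id pairs win among equal weights
  expect_equal(t1$edges[, c("i", "j")],
               data.frame(i = c(1, 1, 2), j = c(2, 3, 4)),
               ignore_attr = TRUE)
})

test_that("tree partition respects minimum size and splits a uniform chain in half", {
  chain <- function(n, depth = rep(1, n)) {
    nodes <- data.frame(id = 1:n, x = seq_len(n), y = 0, depth = depth)
    edges <- data.frame(i = 1:(n - 1), j = 2:n, v_raw = 1, v_norm = 1,
                        w = 1)
    g <- structure(list(nodes = nodes, edges = edges, zone = "ReefCrest"),
                   class = "hex_graph")
    list(g = g,
         t = structure(list(nodes = nodes, edges = edges,
                            zone = "ReefCrest"), class = "spanning_tree"))
  }
  # component smaller than the minimum stays whole
  c150 <- chain(150)
  cl <- partition_tree(c150$t, c150$g, min_size = 200, target_area = 1,
                       hex_area = 1)
  expect_equal(length(unique(cl)), 1)
  # 400 uniform hexagons, min 200 -> exactly two sites of 200
  c400 <- chain(400)
  cl <- partition_tree(c400$t, c400$g, min_size = 200, target_area = 1,
                       hex_area = 1)
  expect_equal(sort(unname(tabulate(cl))), c(200, 200))
  # the split is contiguous along the chain
  expect_equal(length(unique(cl[1:200])), 1)
  # exactly at the minimum: cannot split
  c200 <- chain(200)
  cl <- partition_tree(c200$t, c200$g, min_size = 200, target_area = 1,
                       hex_area = 1)
  expect_equal(length(unique(cl)), 1)
})

test_that("partition prefers splits that separate depth regimes", {
  n <- 60
  depth <- c(rep(2, 30), rep(10, 30))
  nodes <- data.frame(id = 1:n, x = seq_len(n), y = 0, depth = depth)
  edges <- data.frame(i = 1:(n - 1), j = 2:n, v_raw = 1, v_norm = 1, w = 1)
  g <- structure(list(nodes = nodes, edges = edges, zone = "ReefCrest"),
                 class = "hex_graph")
  t <- structure(list(nodes = nodes, edges = edges, zone = "ReefCrest"),
                 class = "spanning_tree")
  cl <- partition_tree(t, g, min_size = 10, target_area = 30, hex_area = 1)
  # the first cut lands exactly at the 2 m / 10 m boundary
  expect_equal(length(unique(cl[1:30])), 1)
  expect_true(!any(cl[1:30] %in% cl[31:60]))
})

test_that("regionalization yields a zone-pure set partition of the map", {
  m <- make_hexagon_map(6, 26000, depth_noise_sd = 0.3, seed = 2)
  sites <- make_site_polygons(m, min_size = 15, target_area = 8e5)
  all_members <- unlist(sites$members)
  expect_setequal(all_members, m$hexes$id)          # covers every hexagon
  expect_equal(length(all_members), length(unique(all_members)))  # disjoint
  for (s in seq_along(sites$members)) {
    zs <- m$hexes$zone[match(sites$members[[s]], m$hexes$id)]
    expect_equal(unique(zs), sites$sites$zone[s])   # zone purity
    expect_true(sites$sites$n_hexagons[s] >= 15 ||
                sites$sites$n_hexagons[s] ==
                  sum(m$hexes$zone == sites$sites$zone[s]))
  }
  expect_equal(sum(sites$sites$area), nrow(m$hexes) * m$hex_area)
})

test_that("site geometry unions conserve area and merge shared edges", {
  m <- make_hexagon_map(2, 26000)
  # single-hexagon site
  s1 <- reefdrift:::new_site_set(
    data.frame(site_id = 1L, zone = "ReefCrest", n_hexagons = 1L,
               area = m$hex_area, centroid_x = m$hexes$x[1],
               centroid_y = m$hexes$y[1]),
    list(m$hexes$id[1]), m)
  g1 <- polygons_to_geometry(s1)
  expect_equal(length(g1[["1"]]), 1)
  expect_equal(reefdrift:::ring_area(g1[["1"]][[1]]), m$hex_area,
               tolerance = 1e-6)
  # two adjacent hexagons merge into one ring of twice the area
  nb <- which(abs(sqrt((m$hexes$x - m$hexes$x[1])^2 +
                       (m$hexes$y - m$hexes$y[1])^2) - sqrt(3) * m$size) <
                1e-6)[1]
  s2 <- reefdrift:::new_site_set(
    data.frame(site_id = 1L, zone = "ReefCrest", n_hexagons = 2L,
               area = 2 * m$hex_area, centroid_x = 0, centroid_y = 0),
    list(c(m$hexes$id[1], m$hexes$id[nb])), m)
  g2 <- polygons_to_geometry(s2)
  expect_equal(length(g2[["1"]]), 1)
  expect_equal(nrow(g2[["1"]][[1]]), 11)  # 10 boundary vertices + closure
  expect_equal(reefdrift:::ring_area(g2[["1"]][[1]]), 2 * m$hex_area,
               tolerance = 1e-6)
  # the whole map as one site
  sall <- reefdrift:::new_site_set(
    data.frame(site_id = 1L, zone = "ReefCrest",
               n_hexagons = nrow(m$hexes), area = nrow(m$hexes) * m$hex_area,
               centroid_x = 0, centroid_y = 0),
    list(m$hexes$id), m)
  gall <- polygons_to_geometry(sall)
  tot <- sum(vapply(gall[["1"]], reefdrift:::ring_area, numeric(1)))
  expect_equal(tot, nrow(m$hexes) * m$hex_area, tolerance = 1e-6)
  # empty site is rejected
  sempty <- sall; sempty$members <- list(integer(0))
  expect_error(polygons_to_geometry(sempty), "empty")
})
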