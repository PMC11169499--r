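#' Delaunay triangulation of planar points
#'
#' Incremental Bowyer-Watson triangulation. Regular lattices (such as hexagon
#' centroids) are maximally degenerate for Delaunay (four or more cocircular
#' points everywhere), so a deterministic symbolic jitter of relative size
#' `jitter` is applied to the coordinates before triangulating; reported
#' triangles/edges index the original points. The edge set of a Delaunay
#' triangulation of >= 3 non-collinear points is always connected, which is
#' the property the regionalization relies on for spatially non-contiguous
#' habitat zones.
#'
#' @param x,y Point coordinates (no duplicates).
#' @param jitter Relative magnitude of the deterministic degeneracy-breaking
#'   perturbation.
#' @return List with `edges` (two-column matrix of point indices, i < j) and
#'   `triangles` (three-column matrix of point indices).
#' @export
delaunay_triangulate <- function(x, y, jitter = 1e-8) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L) return(list(edges = matrix(integer(0), 0, 2),
                          triangles = matrix(integer(0), 0, 3)))
  if (anyDuplicated(cbind(x, y)))
    stop("duplicate points are not allowed", call. = FALSE)
  if (n == 2L) return(list(edges = matrix(c(1L, 2L), 1, 2),
                           triangles = matrix(integer(0), 0, 3)))
  span <- max(max(x) - min(x), max(y) - min(y), 1e-12)
  # deterministic pseudo-random jitter (hash of the index), no RNG state
  frac <- function(v) v - floor(v)
  jx <- (frac(sin(seq_len(n) * 12.9898) * 43758.5453) - 0.5) * jitter * span
  jy <- (frac(sin(seq_len(n) * 78.2330) * 24634.6345) - 0.5) * jitter * span
  px <- x + jx; py <- y + jy

  # super-triangle enclosing everything
  cx <- mean(range(px)); cy <- mean(range(py)); m <- 20 * span
  px <- c(px, cx - 2 * m, cx + 2 * m, cx)
  py <- c(py, cy - m, cy - m, cy + 2 * m)
  sup <- n + 1:3

  tris <- list(c(n + 1L, n + 2L, n + 3L))
  incircle <- function(tr, p) {
    ax <- px[tr[1]] - px[p]; ay <- py[tr[1]] - py[p]
    bx <- px[tr[2]] - px[p]; by <- py[tr[2]] - py[p]
    cx2 <- px[tr[3]] - px[p]; cy2 <- py[tr[3]] - py[p]
    det <- (ax * ax + ay * ay) * (bx * cy2 - cx2 * by) -
           (bx * bx + by * by) * (ax * cy2 - cx2 * ay) +
           (cx2 * cx2 + cy2 * cy2) * (ax * by - bx * ay)
    orient <- (px[tr[2]] - px[tr[1]]) * (py[tr[3]] - py[tr[1]]) -
              (px[tr[3]] - px[tr[1]]) * (py[tr[2]] - py[tr[1]])
    if (orient >= 0) det > 0 else det < 0
  }
  for (p in seq_len(n)) {
    bad <- vapply(tris, incircle, logical(1), p = p)
    bad_tris <- tris[bad]
    tris <- tris[!bad]
    # boundary polygon: edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(bad_tris, function(tr)
      rbind(sort(tr[1:2]), sort(tr[2:3]), sort(tr[c(1, 3)]))))
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    keep <- key %in% names(which(table(key) == 1L))
    for (i in which(keep))
      tris[[length(tris) + 1L]] <- c(edges[i, 1], edges[i, 2], p)
  }
  tris <- tris[!vapply(tris, function(tr) any(tr %in% sup), logical(1))]
  if (length(tris) == 0L) {
    # fully collinear input even after jitter: chain points along their span
    o <- order(px[seq_len(n)], py[seq_len(n)])
    e <- cbind(o[-n], o[-1])
    e <- t(apply(e, 1, sort))
    return(list(edges = e, triangles = matrix(integer(0), 0, 3)))
  }
  tri_mat <- do.call(rbind, tris)
  e <- rbind(tri_mat[, 1:2], tri_mat[, 2:3], tri_mat[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  list(edges = e, triangles = tri_mat)
}
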