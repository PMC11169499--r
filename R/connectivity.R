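#' Per-night connectivity matrix
#'
#' Builds the site-by-site transfer-probability matrix for one spawning
#' night: entry `M[i, j]` is the proportion of larvae released at source
#' site `i` that settled at sink site `j`. Each row sum is therefore at most
#' 1 (a source cannot settle more larvae than it released) while column sums
#' may exceed 1 (a sink can receive from many sources).
#'
#' @param records Settlement records (`source_site`, `sink_site` columns),
#'   e.g. from [settlement_records()].
#' @param released Named vector of released counts per source site (> 0).
#' @param site_order Site ids fixing the row/column order.
#' @param night_id Night identifier attached as an attribute.
#' @return A base matrix with site-id dimnames, class `connectivity_matrix`,
#'   with attributes `released` and `night_id`.
#' @export
build_matrix <- function(records, released, site_order, night_id = 1L) {
  site_order <- as.integer(site_order)
  rel <- released[as.character(site_order)]
  if (anyNA(rel) || any(rel <= 0))
    stop("every site needs a positive released count", call. = FALSE)
  if (nrow(records) > 0 &&
      (!all(records$source_site %in% site_order) ||
       !all(records$sink_site %in% site_order)))
    stop("settlement record references an unknown site", call. = FALSE)
  n <- length(site_order)
  M <- matrix(0, n, n, dimnames = list(site_order, site_order))
  if (nrow(records) > 0) {
    tab <- table(factor(records$source_site, levels = site_order),
                 factor(records$sink_site, levels = site_order))
    M <- unclass(tab) / as.numeric(rel)
    dimnames(M) <- list(site_order, site_order)
  }
  stopifnot(all(rowSums(M) <= 1 + 1e-12))
  structure(M, class = c("connectivity_matrix", "matrix", "array"),
            released = rel, night_id = night_id)
}

#' Percentage of released larvae that settled
#'
#' `100 * total settled / total released`, the Table-1-style settlement
#' percentage for one night and scenario.
#'
#' @param matrix A [build_matrix()] result.
#' @return Percentage in `[0, 100]`.
#' @export
pct_settled <- function(matrix) {
  rel <- attr(matrix, "released")
  if (is.null(rel) || sum(rel) <= 0)
    stop("matrix lacks positive released counts", call. = FALSE)
  100 * sum(unclass(matrix) * as.numeric(rel)) / sum(rel)
}

#' Percentage of sites acting as sinks
#'
#' A sink (settling) site is any site whose column sum is positive; the
#' denominator is all sites in the matrix.
#'
#' @param matrix A [build_matrix()] result.
#' @return Percentage in `[0, 100]`.
#' @export
pct_sink_sites <- function(matrix) {
  100 * sum(colSums(unclass(matrix)) > 0) / ncol(matrix)
}

#' Count network links
#'
#' Number of strictly positive matrix entries; self-recruitment (diagonal)
#' counts as a link (a cyclic edge in the network).
#'
#' @param matrix A [build_matrix()] result.
#' @return Integer link count.
#' @export
count_links <- function(matrix) sum(unclass(matrix) > 0)

#' Per-site source/sink strengths
#'
#' @param matrix A [build_matrix()] result.
#' @return Data frame per site: `source_strength` (row sum: proportion of
#'   released larvae that settled anywhere), `sink_strength` (column sum:
#'   sum of settling fractions received) and `self_recruitment` (diagonal).
#' @export
source_sink_summary <- function(matrix) {
  M <- unclass(matrix)
  data.frame(site_id = as.integer(rownames(M)),
             source_strength = rowSums(M),
             sink_strength = colSums(M),
             self_recruitment = diag(M),
             row.names = NULL)
}

#' Consistent source and sink classification
#'
#' A site is a consistent source if the proportion of its released larvae
#' that settle somewhere is positive on *every* analysed spawning night, and
#' a consistent sink if it receives settlers on every night.
#'
#' @param matrices List of [build_matrix()] results over a common site set.
#' @return Data frame per site: `nights_as_source`, `nights_as_sink`,
#'   `consistent_source`, `consistent_sink`.
#' @export
consistency <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ids <- rownames(matrices[[1]])
  for (m in matrices)
    if (!identical(rownames(m), ids))
      stop("matrices must share one site set", call. = FALSE)
  n_nights <- length(matrices)
  src <- sapply(matrices, function(m) rowSums(unclass(m)) > 0)
  snk <- sapply(matrices, function(m) colSums(unclass(m)) > 0)
  src <- matrix(src, ncol = n_nights); snk <- matrix(snk, ncol = n_nights)
  data.frame(site_id = as.integer(ids),
             nights_as_source = rowSums(src),
             nights_as_sink = rowSums(snk),
             consistent_source = rowSums(src) == n_nights,
             consistent_sink = rowSums(snk) == n_nights,
             row.names = NULL)
}

#' Compare link and sink counts between velocity scenarios
#'
#' Percentage change of the alternative scenario (e.g. full-3D) relative to
#' the reference (e.g. a 2D simulation):
#' `100 * (links_alt - links_ref) / links_ref`, and the same for sink-site
#' counts. `NA` when the reference count is zero (not comparable).
#'
#' @param reference,alternative [build_matrix()] results on the same site
#'   set.
#' @return List `pct_more_links`, `pct_more_sinks`, plus the raw counts.
#' @export
compare_dimensions <- function(reference, alternative) {
  stopifnot(identical(rownames(reference), rownames(alternative)))
  lr <- count_links(reference); la <- count_links(alternative)
  sr <- sum(colSums(unclass(reference)) > 0)
  sa <- sum(colSums(unclass(alternative)) > 0)
  list(links_ref = lr, links_alt = la,
       sinks_ref = sr, sinks_alt = sa,
       pct_more_links = if (lr > 0) 100 * (la - lr) / lr else NA_real_,
       pct_more_sinks = if (sr > 0) 100 * (sa - sr) / sr else NA_real_)
}

#' Export a connectivity network
#'
#' One directed weighted edge per positive matrix entry; nodes carry the
#' site-polygon centroids. Optionally writes GraphML and an edge-list CSV.
#'
#' @param matrix A [build_matrix()] result.
#' @param sites A `site_set` supplying centroids.
#' @param graphml_path,edges_csv_path Optional output paths.
#' @return List with the `igraph` graph, the `edges` data frame
#'   (`from, to, weight`) and the `nodes` data frame.
#' @export
export_network <- function(matrix, sites, graphml_path = NULL,
                           edges_csv_path = NULL) {
  M <- unclass(matrix)
  idx <- which(M > 0, arr.ind = TRUE)
  edges <- data.frame(from = as.integer(rownames(M)[idx[, 1]]),
                      to = as.integer(colnames(M)[idx[, 2]]),
                      weight = M[idx])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(name = as.integer(rownames(M)))
  pos <- sites$sites[match(nodes$name, sites$sites$site_id), ]
  nodes$x <- pos$centroid_x; nodes$y <- pos$centroid_y
  g <- igraph::graph_from_data_frame(
    transform(edges, from = as.character(from), to = as.character(to)),
    directed = TRUE,
    vertices = transform(nodes, name = as.character(name)))
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_csv_path))
    write.csv(edges, edges_csv_path, row.names = FALSE)
  list(graph = g, edges = edges, nodes = nodes)
}

#' Write / read a connectivity matrix as CSV
#'
#' Row/column headers are site ids; released counts are stored in an
#' adjacent `_released.csv` companion so the matrix round-trips completely.
#'
#' @param matrix A [build_matrix()] result.
#' @param path Output CSV path.
#' @return `path` invisibly (writer); a `connectivity_matrix` (reader).
#' @export
write_matrix_csv <- function(matrix, path) {
  M <- unclass(matrix)
  df <- data.frame(site_id = rownames(M), M, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  rel <- attr(matrix, "released")
  write.csv(data.frame(site_id = names(rel), released = as.numeric(rel)),
            sub("\\.csv$", "_released.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- df$site_id
  rel_df <- read.csv(sub("\\.csv$", "_released.csv", path))
  structure(M, class = c("connectivity_matrix", "matrix", "array"),
            released = setNames(rel_df$released, rel_df$site_id),
            night_id = NA_integer_)
}
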