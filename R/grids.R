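#' Rectilinear space-time grid specification
#'
#' Defines the rectilinear grid a gridded velocity field lives on: uniform
#' x/y node coordinates in metres, vertical layer interfaces in metres below
#' the surface (first interface at 0), and uniformly spaced snapshot times in
#' hours since the scenario start (hourly by convention, matching typical
#' hydrodynamic model output).
#'
#' @param x,y Ascending, uniformly spaced node coordinates (metres), >= 2 each.
#' @param layer_interfaces Ascending layer interfaces (metres below surface),
#'   first element 0; `length(layer_interfaces) - 1` layers.
#' @param times Ascending, uniformly spaced snapshot times (hours).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(x, y, layer_interfaces, times) {
  check_axis <- function(v, name, min_n = 2L) {
    if (length(v) < min_n)
      stop("grid axis '", name, "' needs at least ", min_n, " points", call. = FALSE)
    d <- diff(v)
    if (any(d <= 0))
      stop("grid axis '", name, "' must be strictly ascending", call. = FALSE)
    if (length(d) > 1L && max(abs(d - d[1])) > 1e-9 * max(abs(d)))
      stop("grid axis '", name, "' must be uniformly spaced", call. = FALSE)
    invisible(v)
  }
  check_axis(x, "x"); check_axis(y, "y"); check_axis(times, "times")
  if (length(layer_interfaces) < 2L)
    stop("need at least one layer (two interfaces)", call. = FALSE)
  if (abs(layer_interfaces[1]) > 1e-12)
    stop("first layer interface must be 0 (the surface)", call. = FALSE)
  if (any(diff(layer_interfaces) <= 0))
    stop("layer thicknesses must be strictly positive", call. = FALSE)
  structure(
    list(x = as.numeric(x), y = as.numeric(y),
         layer_interfaces = as.numeric(layer_interfaces),
         times = as.numeric(times)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", length(x$x), "x", length(x$y), " nodes, ",
      n_layers(x), " layer(s), ", length(x$times), " times [",
      x$times[1], ", ", x$times[length(x$times)], "] h\n", sep = "")
  invisible(x)
}

n_layers <- function(grid) length(grid$layer_interfaces) - 1L

layer_centres <- function(grid) {
  zi <- grid$layer_interfaces
  (zi[-length(zi)] + zi[-1]) / 2
}

layer_thickness <- function(grid) diff(grid$layer_interfaces)

grid_bounds <- function(grid) {
  c(xmin = grid$x[1], xmax = grid$x[length(grid$x)],
    ymin = grid$y[1], ymax = grid$y[length(grid$y)])
}
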