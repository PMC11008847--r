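#' Construct a circular cell
#'
#' Builds a cell whose cortex is a regular `n_nodes`-gon, counter-clockwise,
#' with polygon (not circumscribed-circle) area exactly equal to `area`. The
#' construction-time node spacing `perimeter / n_nodes` is stored as the
#' cell's reference spacing and drives cortical remodeling for the rest of
#' the simulation.
#'
#' @param center numeric length-2, (x, z) centre of the cell.
#' @param area target enclosed area (> 0).
#' @param n_nodes number of cortex nodes (>= 8; default 100).
#' @param cycle_length cell-cycle duration in hours (NA disables division).
#' @return An object of class `"epicell"`: a list with `nodes` (an n x 2
#'   matrix, columns x and z), `A0` (preferred area), `ref_spacing`,
#'   `cycle_length`, `age` (hours) and `dividing` flag.
#' @examples
#' cell <- make_circular_cell(c(0, 2), area = 1, n_nodes = 100)
#' polygon_area(cell) # 1 to within 1e-9
#' @export
make_circular_cell <- function(center = c(0, 0), area = 1, n_nodes = 100L,
                               cycle_length = NA_real_) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop("area must be a positive finite scalar", call. = FALSE)
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 8)
    stop("n_nodes must be at least 8", call. = FALSE)
  n <- as.integer(n_nodes)
  # regular n-gon area = n/2 r^2 sin(2 pi / n); solve for the circumradius
  r <- sqrt(2 * area / (n * sin(2 * pi / n)))
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  nodes <- cbind(x = center[1] + r * cos(theta),
                 z = center[2] + r * sin(theta))
  cell <- structure(list(
    nodes = nodes,
    A0 = area,
    ref_spacing = 2 * n * r * sin(pi / n) / n,
    cycle_length = cycle_length,
    age = 0,
    dividing = is.finite(cycle_length)
  ), class = "epicell")
  cell
}

#' @export
print.epicell <- function(x, ...) {
  cat(sprintf("<epicell: %d nodes, area %.4f (A0 %.3f), age %.2f h%s>\n",
              nrow(x$nodes), polygon_area(x), x$A0, x$age,
              if (isTRUE(x$dividing)) sprintf(", divides at %.2f h",
                                              x$cycle_length) else ""))
  invisible(x)
}

#' Construct the rigid substrate
#'
#' The substrate is a fixed line of nodes on the z = 0 axis. Its spacing is
#' conventionally set to the initial node spacing of a standard cell, and its
#' length is what confines a colony: adhesion bonds cannot form beyond the
#' last node, so spreading halts there and substrate length controls density.
#'
#' @param x_min,x_max extent of the substrate (`x_max > x_min`).
#' @param spacing node spacing (> 0); the last interval may be shorter.
#' @return An object of class `"episubstrate"`: list with `nodes`
#'   (m x 2 matrix, z = 0) and `spacing`.
#' @examples
#' sub <- make_substrate(0, 1, 0.1) # 11 nodes
#' @export
make_substrate <- function(x_min, x_max, spacing) {
  if (!is.numeric(x_min) || !is.numeric(x_max) || x_max <= x_min)
    stop("x_max must exceed x_min", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be positive", call. = FALSE)
  xs <- seq(x_min, x_max, by = spacing)
  if (xs[length(xs)] < x_max - 1e-12 * max(1, abs(x_max)))
    xs <- c(xs, x_max)
  structure(list(nodes = cbind(x = xs, z = rep(0, length(xs))),
                 spacing = spacing),
            class = "episubstrate")
}

#' @export
print.episubstrate <- function(x, ...) {
  cat(sprintf("<episubstrate: %d nodes on [%.3f, %.3f], spacing %.4f>\n",
              nrow(x$nodes), x$nodes[1, 1], x$nodes[nrow(x$nodes), 1],
              x$spacing))
  invisible(x)
}

node_matrix <- function(cell) {
  if (inherits(cell, "epicell")) cell$nodes else as.matrix(cell)
}

#' Signed shoelace sum of a closed polyline
#'
#' Returns `sum_k (x_k z_{k+1} - x_{k+1} z_k)`, i.e. twice the signed area;
#' positive for counter-clockwise orientation. This is the quantity entering
#' the area term of the internal force.
#'
#' @param cell an `epicell` or an n x 2 coordinate matrix.
#' @return Signed scalar.
#' @export
polygon_signed_sum <- function(cell) {
  P <- node_matrix(cell)
  x <- P[, 1]; z <- P[, 2]
  xn <- c(x[-1], x[1]); zn <- c(z[-1], z[1])
  sum(x * zn - xn * z)
}

#' Enclosed area of a cell polygon
#'
#' Shoelace area `|sum_k (x_k z_{k+1} - x_{k+1} z_k)| / 2`, independent of
#' node ordering direction. Use [polygon_signed_sum()] when the orientation
#' sign is needed.
#'
#' @inheritParams polygon_signed_sum
#' @return Non-negative scalar area.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' polygon_area(sq) # 1
#' @export
polygon_area <- function(cell) abs(polygon_signed_sum(cell)) / 2

#' Perimeter of a cell polygon
#'
#' Sum of consecutive node distances including the closing edge.
#'
#' @inheritParams polygon_signed_sum
#' @return Non-negative scalar length.
#' @export
polygon_perimeter <- function(cell) {
  P <- node_matrix(cell)
  Q <- P[c(2:nrow(P), 1L), , drop = FALSE]
  sum(sqrt(rowSums((Q - P)^2)))
}

polygon_centroid <- function(cell) colMeans(node_matrix(cell))

#' Circularity of a cell polygon
#'
#' `4 pi A / P^2`; 1 for a circle, lower for elongated shapes.
#'
#' @inheritParams polygon_signed_sum
#' @return Scalar in (0, 1] for simple polygons.
#' @export
polygon_circularity <- function(cell) {
  4 * pi * polygon_area(cell) / polygon_perimeter(cell)^2
}

#' Width/height aspect ratio of a cell polygon
#'
#' Bounding-box x-extent divided by z-extent; used to distinguish spread
#' (flattened, ratio > 2) from rounded (ratio near 1) cells.
#'
#' @inheritParams polygon_signed_sum
#' @return Positive scalar.
#' @export
cell_aspect_ratio <- function(cell) {
  P <- node_matrix(cell)
  diff(range(P[, 1])) / diff(range(P[, 2]))
}
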