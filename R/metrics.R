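#' Per-cell connection fractions
#'
#' The proportion of a cell's cortex nodes participating in cell-substrate
#' or cell-cell adhesion, used as proxies for the lengths of the
#' cell-substrate and cell-cell interfaces.
#'
#' @param cs_bonded logical per-node vector: node holds a substrate bond.
#' @param cc_bonded logical per-node vector: node holds at least one
#'   attractive cell-cell bond.
#' @return Named numeric vector `c(f_cs = , f_cc = )`, each in \[0, 1\].
#' @export
connection_fractions <- function(cs_bonded, cc_bonded) {
  stopifnot(length(cs_bonded) == length(cc_bonded))
  n <- length(cs_bonded)
  c(f_cs = sum(cs_bonded) / n, f_cc = sum(cc_bonded) / n)
}

#' Layer density
#'
#' Linear cell density is the number of cells divided by the occupied
#' substrate span (the x-extent between the outermost substrate-bonded cell
#' nodes). Because the simulation is a 2D cross-section of a 3D layer,
#' density is reported in arbitrary units obtained by scaling the linear
#' density: with one model length unit = 10 um, `cells/mm^2 = (cells/mm)^2`
#' and `Arb = cells/mm^2 / 1000`. Four cells spanning 47.8 um give 83.7
#' cells/mm, i.e. 7.0e3 cells/mm^2 = 7.0 Arb, anchoring the simulated
#' density scale to the MDCK scale where the apical:basal ratio declines.
#'
#' @param n_cells number of cells in the layer.
#' @param span occupied substrate span in model length units.
#' @return List with `linear_per_mm`, `cells_per_mm2`, `density_arb`.
#' @examples
#' layer_density(4, 4.78)$density_arb # 7.0
#' @export
layer_density <- function(n_cells, span) {
  if (!is.finite(span) || span <= 0 || n_cells < 1)
    return(list(linear_per_mm = NA_real_, cells_per_mm2 = NA_real_,
                density_arb = NA_real_))
  linear <- n_cells / (span * 0.01) # 1 model unit = 10 um = 0.01 mm
  list(linear_per_mm = linear,
       cells_per_mm2 = linear^2,
       density_arb = linear^2 / 1000)
}

occupied_span <- function(cells, sub_bonds) {
  if (!nrow(sub_bonds)) return(NA_real_)
  xs <- mapply(function(i, j) node_matrix(cells[[i]])[j, 1],
               sub_bonds$cell, sub_bonds$node)
  diff(range(xs))
}

#' Apical-to-basal surface length ratio
#'
#' The basal surface is the polyline arc over the contiguous run of
#' substrate-bonded nodes; the apical surface is the longest polyline arc
#' of nodes that participate in neither substrate nor cell-cell adhesion
#' (the free top arc, defined by exclusion from cell-cell borders). Returns
#' `NA` (undefined) when the cell has no substrate bonds.
#'
#' @param cell an `epicell` (or n x 2 coordinate matrix).
#' @param cs_bonded,cc_bonded logical per-node adhesion indicators.
#' @return Scalar ratio apical / basal, or `NA`.
#' @export
apical_basal_ratio <- function(cell, cs_bonded, cc_bonded) {
  P <- node_matrix(cell)
  n <- nrow(P)
  stopifnot(length(cs_bonded) == n, length(cc_bonded) == n)
  if (!any(cs_bonded)) return(NA_real_)
  edge_len <- function(a, b) sqrt(sum((P[a, ] - P[b, ])^2))
  # basal: cyclic run spanning all bonded nodes, excluding the largest gap
  b <- which(cs_bonded)
  m <- length(b)
  basal <- 0
  if (m >= 2) {
    gaps <- c(diff(b), b[1] + n - b[m])
    k <- which.max(gaps)
    # traverse from b[k+1] (cyclically) forward to b[k] through the others
    start <- if (k == m) b[1] else b[k + 1L]
    end <- b[k]
    idx <- if (start <= end) start:end else c(start:n, 1:end)
    for (t in seq_len(length(idx) - 1L))
      basal <- basal + edge_len(idx[t], idx[t + 1L])
  }
  if (basal == 0) return(NA_real_)
  # apical: longest contiguous free run
  free <- !cs_bonded & !cc_bonded
  if (!any(free)) return(0)
  if (all(free)) {
    apical <- polygon_perimeter(P)
    return(apical / basal)
  }
  # walk runs cyclically, starting just after a non-free node
  start <- which(!free)[1]
  ord <- ((start:(start + n - 1L) - 1L) %% n) + 1L
  best <- 0; cur <- 0; prev <- NA_integer_
  for (j in ord) {
    if (free[j]) {
      if (!is.na(prev)) cur <- cur + edge_len(prev, j)
      prev <- j
    } else {
      best <- max(best, cur)
      cur <- 0; prev <- NA_integer_
    }
  }
  best <- max(best, cur)
  best / basal
}

#' Classify layer architecture
#'
#' A layer transitions from Immature to Intermediate when lateral surfaces
#' develop, i.e. when about 10% of the cell surface participates in
#' cell-cell adhesion (more than one cell-cell connection per cell given
#' ~100 nodes). The mean cell-cell connection fraction is taken over
#' interior cells (colony edges are Immature by construction); the boundary
#' value classifies as Intermediate.
#'
#' @param f_cc numeric vector of per-cell cell-cell connection fractions.
#' @param interior optional logical mask of interior cells (default: all).
#' @param cc_threshold classification threshold (default 0.10).
#' @return `"Intermediate"` or `"Immature"`.
#' @examples
#' classify_architecture(c(0.12, 0.18, 0.02), c(TRUE, TRUE, FALSE))
#' @export
classify_architecture <- function(f_cc, interior = NULL,
                                  cc_threshold = 0.10) {
  if (is.null(interior)) interior <- rep(TRUE, length(f_cc))
  m <- mean(f_cc[interior])
  if (is.finite(m) && m >= cc_threshold) "Intermediate" else "Immature"
}

#' Shape index from circularity
#'
#' The dimensionless shape index `S0 = P / sqrt(A) = sqrt(4 pi /
#' circularity)`; 3.81 predicts the jamming transition in 2D vertex models,
#' and the circularity plateau of 0.84 observed in densifying MDCK layers
#' maps to 3.87.
#'
#' @param circularity values in (0, 1].
#' @return Shape index values.
#' @examples
#' shape_index(1) # sqrt(4 * pi), a circle
#' shape_index(pi / 4) # 4, a square
#' @export
shape_index <- function(circularity) {
  if (any(!is.finite(circularity)) || any(circularity <= 0) ||
      any(circularity > 1))
    stop("circularity must lie in (0, 1]", call. = FALSE)
  sqrt(4 * pi / circularity)
}

#' Density at the Immature-to-Intermediate transition
#'
#' Linearly interpolates the first crossing of the cell-cell connection
#' threshold along a densification sweep.
#'
#' @param density densities, sorted increasing.
#' @param f_cc mean cell-cell connection fraction at each density.
#' @param cc_threshold the crossing level (default 0.10).
#' @return The interpolated crossing density, or `NA` if never crossed.
#' @examples
#' transition_density(c(2, 3, 4), c(0.04, 0.09, 0.13)) # 3.25
#' @export
transition_density <- function(density, f_cc, cc_threshold = 0.10) {
  stopifnot(length(density) == length(f_cc))
  if (is.unsorted(density))
    stop("density must be sorted increasing", call. = FALSE)
  hit <- which(f_cc >= cc_threshold)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(density[1])
  d0 <- density[i - 1L]; d1 <- density[i]
  f0 <- f_cc[i - 1L]; f1 <- f_cc[i]
  d0 + (cc_threshold - f0) / (f1 - f0) * (d1 - d0)
}

#' Layer metrics for one simulation state
#'
#' Recomputes bonds for the state's current positions (using the carried
#' contact history, exactly as the engine would at its next step) and
#' measures the layer: per-cell connection fractions and apical:basal
#' ratio, occupied-span density, and the Immature/Intermediate label from
#' the interior-cell mean cell-cell connection fraction. Interior cells are
#' all but the leftmost and rightmost (by centroid) when there are at least
#' three cells.
#'
#' @param state an `episim` state.
#' @return data.frame with one row per cell: `step`, `time_h`, `cell`,
#'   `n_nodes`, `f_cs`, `f_cc`, `apical_basal`, `interior`, `span`,
#'   `linear_per_mm`, `cells_per_mm2`, `density_arb`, `architecture`.
#' @export
frame_metrics <- function(state) {
  params <- state$params
  bonds <- state_bonds(state)
  nc <- length(state$cells)
  cs_flags <- vector("list", nc)
  cc_flags <- vector("list", nc)
  for (i in seq_len(nc)) {
    n <- nrow(node_matrix(state$cells[[i]]))
    cs <- rep(FALSE, n); cc <- rep(FALSE, n)
    sb <- bonds$sub_bonds
    cs[sb$node[sb$cell == i]] <- TRUE
    cb <- bonds$cell_bonds
    if (nrow(cb)) {
      att <- cb[cb$attractive, , drop = FALSE]
      cc[att$node_j[att$cell_i == i]] <- TRUE
      cc[att$node_k[att$cell_l == i]] <- TRUE
    }
    cs_flags[[i]] <- cs
    cc_flags[[i]] <- cc
  }
  fr <- t(vapply(seq_len(nc), function(i)
    connection_fractions(cs_flags[[i]], cc_flags[[i]]), numeric(2)))
  ab <- vapply(seq_len(nc), function(i)
    apical_basal_ratio(state$cells[[i]], cs_flags[[i]], cc_flags[[i]]),
    numeric(1))
  cx <- vapply(state$cells, function(cl) mean(node_matrix(cl)[, 1]),
               numeric(1))
  interior <- rep(TRUE, nc)
  if (nc >= 3) interior[c(which.min(cx), which.max(cx))] <- FALSE
  span <- occupied_span(state$cells, bonds$sub_bonds)
  dens <- layer_density(nc, span)
  label <- classify_architecture(fr[, "f_cc"], interior,
                                 params$cc_threshold)
  data.frame(
    step = state$step_index,
    time_h = steps_to_hours(state$step_index, params),
    cell = seq_len(nc),
    n_nodes = vapply(state$cells, function(cl) nrow(node_matrix(cl)),
                     integer(1)),
    f_cs = fr[, "f_cs"],
    f_cc = fr[, "f_cc"],
    apical_basal = ab,
    interior = interior,
    span = span,
    linear_per_mm = dens$linear_per_mm,
    cells_per_mm2 = dens$cells_per_mm2,
    density_arb = dens$density_arb,
    architecture = label,
    row.names = NULL
  )
}

#' Metrics table for a whole trajectory
#'
#' Applies [frame_metrics()] to every recorded frame; identical whether the
#' trajectory was just produced by [run_scenario()] or re-read from disk.
#'
#' @param traj a trajectory object (see [write_trajectory()]).
#' @return data.frame, one row per cell per frame.
#' @export
trajectory_metrics <- function(traj) {
  out <- lapply(traj$frames, function(f) frame_metrics(frame_state(traj, f)))
  do.call(rbind, out)
}
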