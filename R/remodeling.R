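#' Cortical remodeling: node insertion and removal
#'
#' Keeps the cortex discretization approximately uniform as the cell
#' deforms. One pass over the current edges: an edge longer than twice the
#' cell's reference spacing gets a new node at its bisection; for an edge
#' shorter than half the reference spacing, whichever of its two endpoint
#' nodes is closer to its other neighbour is removed. The reference spacing
#' is the construction-time node spacing and never changes (using the
#' instantaneous mean would let the discretization drift as the cell
#' stretches). Removals that would drop the cell below 8 nodes are skipped
#' with a warning.
#'
#' @param cell an `epicell`.
#' @return The remodeled `epicell`.
#' @export
remodel_cortex <- function(cell) {
  P <- cell$nodes
  n <- nrow(P)
  ref <- cell$ref_spacing
  ip <- c(2:n, 1L)
  im <- c(n, 1:(n - 1L))
  elen <- sqrt(rowSums((P[ip, , drop = FALSE] - P)^2)) # edge j: j -> j+1
  insert_after <- elen > 2 * ref
  remove <- rep(FALSE, n)
  short <- which(elen < 0.5 * ref)
  for (j in short) {
    a <- j; b <- ip[j]
    # distance of each endpoint to its *other* neighbour
    da <- sqrt(sum((P[a, ] - P[im[a], ])^2))
    db <- sqrt(sum((P[b, ] - P[ip[b], ])^2))
    remove[if (da <= db) a else b] <- TRUE
  }
  n_after <- n - sum(remove) + sum(insert_after)
  if (sum(remove) && n_after < 8L) {
    warning("cortex remodeling skipped removals to keep >= 8 nodes")
    remove[] <- FALSE
  }
  if (!any(remove) && !any(insert_after)) return(cell)
  out <- matrix(0, n + sum(insert_after), 2)
  k <- 0L
  for (j in seq_len(n)) {
    if (!remove[j]) {
      k <- k + 1L
      out[k, ] <- P[j, ]
    }
    if (insert_after[j]) {
      k <- k + 1L
      out[k, ] <- (P[j, ] + P[ip[j], ]) / 2
    }
  }
  cell$nodes <- out[seq_len(k), , drop = FALSE]
  colnames(cell$nodes) <- c("x", "z")
  cell
}

#' Division program: growth ramp and adhesion cessation
#'
#' Over the final hour of its cycle a cell doubles in (preferred) size and
#' ceases cell-cell adhesion. The preferred-area target ramps linearly from
#' `A0` at one hour before division to `2 A0` at division time, and the
#' cell's base `gamma_cc` is zero throughout that hour (short-range `R_cc`
#' repulsion stays on; repulsion is adhesion-independent). Cells without a
#' finite cycle length never change.
#'
#' @param cell an `epicell` whose `age` (hours) is current.
#' @param params a [model_params()] object.
#' @param growth_window duration of the growth/cessation window in hours.
#' @return The cell with fields `A0_target` (preferred area used by the
#'   internal forces this step), `gamma_cc_on` (FALSE during the final
#'   hour) and `division_due` (TRUE once `age >= cycle_length`).
#' @export
update_division_program <- function(cell, params, growth_window = 1) {
  cell$A0_target <- cell$A0
  cell$gamma_cc_on <- TRUE
  cell$division_due <- FALSE
  if (!isTRUE(cell$dividing) || !is.finite(cell$cycle_length)) return(cell)
  start <- cell$cycle_length - growth_window
  if (cell$age >= start) {
    tau <- min(1, max(0, (cell$age - start) / growth_window))
    cell$A0_target <- cell$A0 * (1 + tau)
    cell$gamma_cc_on <- FALSE
  }
  if (cell$age >= cell$cycle_length) cell$division_due <- TRUE
  cell
}

#' Planar cell division
#'
#' Splits the polygon along the chord between its topmost and bottommost
#' (in z) nodes, producing planar divisions: each daughter receives its arc
#' plus the two chord endpoints, then undergoes repeated cortical
#' remodeling until no further insertions occur, which populates the
#' cytokinetic plane with nodes at roughly the reference spacing. Daughter
#' preferred areas reset to the parent's base `A0`, ages reset to zero.
#' Enclosed area is conserved exactly by the split (bisection inserts lie
#' on the chord). If the topmost and bottommost nodes coincide the division
#' is aborted with a warning and `NULL` is returned.
#'
#' @param cell the dividing `epicell` (at twice its base preferred area).
#' @param daughter_cycle_length cycle length assigned to the daughters
#'   (hours); default 4, the upper bound of the initial-cell distribution.
#' @param daughters_divide should the daughters re-enter the cell cycle?
#' @return List of two `epicell` daughters, or `NULL` if degenerate.
#' @export
divide_cell <- function(cell, daughter_cycle_length = 4,
                        daughters_divide = FALSE) {
  P <- cell$nodes
  n <- nrow(P)
  itop <- which.max(P[, 2])
  ibot <- which.min(P[, 2])
  if (itop == ibot) {
    warning("degenerate division axis (topmost == bottommost node); aborted")
    return(NULL)
  }
  cyc_seq <- function(a, b) { # cyclic index sequence a..b inclusive
    if (a <= b) a:b else c(a:n, 1:b)
  }
  arcs <- list(cyc_seq(itop, ibot), cyc_seq(ibot, itop))
  daughters <- lapply(arcs, function(idx) {
    d <- cell
    d$nodes <- P[idx, , drop = FALSE]
    d$A0 <- cell$A0
    d$age <- 0
    d$cycle_length <- if (daughters_divide) daughter_cycle_length
                      else NA_real_
    d$dividing <- daughters_divide
    d$A0_target <- NULL; d$gamma_cc_on <- NULL; d$division_due <- NULL
    # populate the cytokinetic plane: remodel until no insertion happens
    for (iter in 1:64) {
      n_before <- nrow(d$nodes)
      d <- remodel_cortex(d)
      if (nrow(d$nodes) <= n_before) break
    }
    d
  })
  daughters
}

#' Sample initial cell-cycle lengths
#'
#' Cycle durations of the initial cells are i.i.d. uniform on [0, 4] hours.
#' Sampling uses R's global RNG stream; pass `seed` (or call `set.seed()`
#' beforehand) for reproducibility.
#'
#' @param n number of cells.
#' @param seed optional integer seed applied before sampling.
#' @param max_hours upper bound of the uniform distribution.
#' @return Numeric vector of `n` cycle lengths in hours.
#' @export
sample_initial_cycles <- function(n, seed = NULL, max_hours = 4) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, 0, max_hours)
}
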