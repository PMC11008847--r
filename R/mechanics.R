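#' Internal (area + perimeter) forces on a cell's nodes
#'
#' The cortex tends its enclosed area A toward the preferred value A0 while
#' minimizing its perimeter L, through the energy
#' `E = 1/2 k_A (A - A0)^2 + 1/2 k_L L^2`. The returned force on node j is
#' the negative gradient of E with respect to that node's coordinates:
#' an area term `-k_A (A - A0) * sign(S) * 1/2 * (z_{j+1} - z_{j-1},
#' -(x_{j+1} - x_{j-1}))` (S the signed shoelace sum) plus a perimeter term
#' `-k_L L (t_{j-1} - t_j)` built from the unit tangents of the two edges
#' meeting at j. A zero-length edge contributes a zero tangent (with a
#' warning). The forces sum to zero over the cell (translation invariance).
#'
#' @param cell an `epicell` (or n x 2 coordinate matrix).
#' @param params a [model_params()] object.
#' @param A0 optional override of the preferred area (used during the
#'   division growth ramp); defaults to the cell's own `A0`.
#' @return An n x 2 matrix of force components (x, z).
#' @export
internal_forces <- function(cell, params, A0 = NULL) {
  P <- node_matrix(cell)
  if (is.null(A0)) A0 <- if (inherits(cell, "epicell")) cell$A0 else params$A0
  n <- nrow(P)
  x <- P[, 1]; z <- P[, 2]
  ip <- c(2:n, 1L)   # j + 1 (cyclic)
  im <- c(n, 1:(n - 1L)) # j - 1
  S <- sum(x * z[ip] - x[ip] * z)
  A <- abs(S) / 2
  sgn <- if (S >= 0) 1 else -1
  # edge j: from node j to node j+1
  ex <- x[ip] - x
  ez <- z[ip] - z
  elen <- sqrt(ex^2 + ez^2)
  bad <- elen == 0
  if (any(bad)) {
    warning("degenerate (zero-length) cortex edge; tangent treated as zero")
    elen[bad] <- 1 # avoid 0/0; numerator is zero anyway
  }
  tx <- ex / elen; tz <- ez / elen # unit tangent of edge j
  L <- sum(elen[!bad])
  coefA <- params$k_A * (A - A0) * sgn / 2
  Fx <- -coefA * (z[ip] - z[im]) - params$k_L * L * (tx[im] - tx)
  Fz <- coefA * (x[ip] - x[im]) - params$k_L * L * (tz[im] - tz)
  cbind(x = Fx, z = Fz)
}

#' Match cell-substrate adhesion bonds
#'
#' Adhesion springs connect a cell node and a substrate node when their
#' distance is below `d_cs`, under mutual-nearest exclusivity: each cell
#' node may bond only its nearest substrate node, and each substrate node
#' only its nearest cell node (across all cells). Bonds are stateless; they
#' are recomputed from current positions every step, so a spring "breaks"
#' simply by exiting the interaction distance.
#'
#' @param cells list of `epicell` objects.
#' @param substrate an `episubstrate`.
#' @param params a [model_params()] object.
#' @return data.frame with columns `cell`, `node`, `sub` (indices) and
#'   `dist`.
#' @export
match_substrate_bonds <- function(cells, substrate, params) {
  S <- substrate$nodes
  m <- nrow(S)
  allx <- numeric(0); allz <- numeric(0); allcell <- integer(0)
  allnode <- integer(0)
  for (i in seq_along(cells)) {
    P <- node_matrix(cells[[i]])
    allx <- c(allx, P[, 1]); allz <- c(allz, P[, 2])
    allcell <- c(allcell, rep.int(i, nrow(P)))
    allnode <- c(allnode, seq_len(nrow(P)))
  }
  if (!length(allx))
    return(data.frame(cell = integer(0), node = integer(0),
                      sub = integer(0), dist = numeric(0)))
  # nearest substrate node of each cell node: substrate is sorted in x, and
  # all substrate nodes share z = 0, so nearest overall = nearest in x
  k <- findInterval(allx, S[, 1], all.inside = TRUE)
  k <- ifelse(abs(allx - S[k, 1]) <= abs(S[pmin(k + 1L, m), 1] - allx),
              k, pmin(k + 1L, m))
  d <- sqrt((allx - S[k, 1])^2 + allz^2)
  cand <- which(d < params$d_cs)
  if (!length(cand))
    return(data.frame(cell = integer(0), node = integer(0),
                      sub = integer(0), dist = numeric(0)))
  # substrate-side exclusivity: nearest cell node of substrate node k must
  # be this node. Compute the true per-substrate-node minimum distance over
  # *all* cell nodes within range (not only those whose nearest is k).
  best_d <- rep(Inf, m); best_j <- rep(NA_integer_, m)
  for (j in seq_along(allx)) {
    lo <- findInterval(allx[j] - params$d_cs, S[, 1]) + 1L
    hi <- findInterval(allx[j] + params$d_cs, S[, 1])
    if (hi < lo) next
    ks <- lo:hi
    ds <- sqrt((allx[j] - S[ks, 1])^2 + allz[j]^2)
    upd <- ds < best_d[ks]
    best_d[ks[upd]] <- ds[upd]
    best_j[ks[upd]] <- j
  }
  keep <- cand[best_j[k[cand]] == cand]
  data.frame(cell = allcell[keep], node = allnode[keep],
             sub = k[keep], dist = d[keep])
}

#' Cell-substrate adhesion forces
#'
#' Linear-spring pull toward the bonded substrate node:
#' `F = -gamma_cs_eff * (|p - s| - l_cs) * (p - s)/|p - s|` on each bonded
#' cell node. The substrate is rigid and absorbs the reaction. A bond of
#' zero length contributes no force.
#'
#' @param cells list of `epicell` objects.
#' @param substrate an `episubstrate`.
#' @param bonds data.frame from [match_substrate_bonds()].
#' @param params a [model_params()] object.
#' @param gamma_cs_eff numeric vector of per-cell effective adhesion
#'   strengths (defaults to the base `gamma_cs` for every cell).
#' @return List of n_i x 2 force matrices, one per cell.
#' @export
substrate_adhesion_forces <- function(cells, substrate, bonds, params,
                                      gamma_cs_eff = NULL) {
  if (is.null(gamma_cs_eff))
    gamma_cs_eff <- rep(params$gamma_cs, length(cells))
  F <- lapply(cells, function(cl) {
    P <- node_matrix(cl)
    matrix(0, nrow(P), 2)
  })
  if (!nrow(bonds)) return(F)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$cell[b]; j <- bonds$node[b]; k <- bonds$sub[b]
    p <- node_matrix(cells[[i]])[j, ]
    s <- substrate$nodes[k, ]
    d <- bonds$dist[b]
    if (d == 0) next
    u <- (p - s) / d
    F[[i]][j, ] <- F[[i]][j, ] - gamma_cs_eff[i] * (d - params$l_cs) * u
  }
  F
}

#' Match cell-cell bonds
#'
#' Every node pair (j of cell i, k of cell l != i) closer than the pair's
#' interaction distance is recorded; there is no exclusivity (the force law
#' is a double sum over neighbouring cells and their nodes). A pair at
#' distance above `l_cc` is attractive; below `l_cc` it is repulsive. The
#' per-pair interaction distance is the larger of the two cells' effective
#' `d_cc` (contact feedback extends the search range of a cell that already
#' touches a neighbour).
#'
#' @param cells list of `epicell` objects.
#' @param params a [model_params()] object.
#' @param d_cc_eff per-cell effective interaction distances (defaults to the
#'   base `d_cc`).
#' @return data.frame with columns `cell_i`, `node_j`, `cell_l`, `node_k`
#'   (with `cell_i < cell_l`), `dist` and logical `attractive`.
#' @export
match_cell_bonds <- function(cells, params, d_cc_eff = NULL) {
  nc <- length(cells)
  if (is.null(d_cc_eff)) d_cc_eff <- rep(params$d_cc, nc)
  out <- list()
  if (nc >= 2) {
    ranges <- lapply(cells, function(cl) range(node_matrix(cl)[, 1]))
    for (i in seq_len(nc - 1L)) {
      Pi <- node_matrix(cells[[i]])
      for (l in (i + 1L):nc) {
        d <- max(d_cc_eff[i], d_cc_eff[l])
        if (ranges[[i]][1] > ranges[[l]][2] + d ||
            ranges[[l]][1] > ranges[[i]][2] + d) next
        Pl <- node_matrix(cells[[l]])
        dx <- outer(Pi[, 1], Pl[, 1], "-")
        dz <- outer(Pi[, 2], Pl[, 2], "-")
        dist <- sqrt(dx^2 + dz^2)
        hit <- which(dist < d, arr.ind = TRUE)
        if (!nrow(hit)) next
        out[[length(out) + 1L]] <- data.frame(
          cell_i = i, node_j = hit[, 1], cell_l = l, node_k = hit[, 2],
          dist = dist[hit],
          attractive = dist[hit] > params$l_cc
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(cell_i = integer(0), node_j = integer(0),
                      cell_l = integer(0), node_k = integer(0),
                      dist = numeric(0), attractive = logical(0)))
  do.call(rbind, out)
}

#' Cell-cell adhesion and repulsion forces
#'
#' For an attractive pair (distance d in (`l_cc`, `d_cc`)) each endpoint
#' feels `-gamma * (d - l_cc) * u` along the unit separation vector u; for a
#' repulsive pair (d < `l_cc`) the strength is the adhesion-independent
#' constant `R_cc`, and `(d - l_cc) < 0` makes the force push the nodes
#' apart. The per-bond attractive strength is the smaller of the two cells'
#' effective `gamma_cc`, which keeps each bond's two forces exactly equal
#' and opposite and makes a cell that has ceased adhesion (e.g. while
#' dividing) exert none. Coincident nodes contribute no force (warning).
#'
#' @param cells list of `epicell` objects.
#' @param bonds data.frame from [match_cell_bonds()].
#' @param params a [model_params()] object.
#' @param gamma_cc_eff per-cell effective adhesion strengths (defaults to
#'   the base `gamma_cc`).
#' @return List of n_i x 2 force matrices, one per cell.
#' @export
cell_adhesion_forces <- function(cells, bonds, params, gamma_cc_eff = NULL) {
  if (is.null(gamma_cc_eff))
    gamma_cc_eff <- rep(params$gamma_cc, length(cells))
  F <- lapply(cells, function(cl) matrix(0, nrow(node_matrix(cl)), 2))
  if (!nrow(bonds)) return(F)
  if (any(bonds$dist == 0))
    warning("coincident nodes in a cell-cell bond; force set to zero")
  for (b in seq_len(nrow(bonds))) {
    d <- bonds$dist[b]
    if (d == 0) next
    i <- bonds$cell_i[b]; j <- bonds$node_j[b]
    l <- bonds$cell_l[b]; k <- bonds$node_k[b]
    p <- node_matrix(cells[[i]])[j, ]
    q <- node_matrix(cells[[l]])[k, ]
    u <- (p - q) / d
    g <- if (bonds$attractive[b]) min(gamma_cc_eff[i], gamma_cc_eff[l])
         else params$R_cc
    f <- -g * (d - params$l_cc) * u
    F[[i]][j, ] <- F[[i]][j, ] + f
    F[[l]][k, ] <- F[[l]][k, ] - f
  }
  F
}

#' Gravity forces
#'
#' A constant downward force `(0, -C_G)` acts on every node of a cell that
#' has no path to the substrate through the current bond network. The path
#' search treats cells and the substrate as graph vertices, with an edge for
#' any substrate bond and any cell-cell bond (attractive or repulsive):
#' gravity is orders of magnitude weaker than the other forces and is
#' dropped once a cell rests on the substrate or on a neighbour connected
#' to it.
#'
#' @param cells list of `epicell` objects.
#' @param sub_bonds data.frame from [match_substrate_bonds()].
#' @param cell_bonds data.frame from [match_cell_bonds()].
#' @param params a [model_params()] object.
#' @return List of n_i x 2 force matrices, one per cell.
#' @export
gravity_forces <- function(cells, sub_bonds, cell_bonds, params) {
  grounded <- cells_with_substrate_path(length(cells), sub_bonds, cell_bonds)
  lapply(seq_along(cells), function(i) {
    n <- nrow(node_matrix(cells[[i]]))
    if (grounded[i]) matrix(0, n, 2)
    else cbind(rep(0, n), rep(-params$C_G, n))
  })
}

cells_with_substrate_path <- function(n_cells, sub_bonds, cell_bonds) {
  grounded <- seq_len(n_cells) %in% sub_bonds$cell
  repeat {
    newly <- grounded[cell_bonds$cell_i] | grounded[cell_bonds$cell_l]
    before <- grounded
    grounded[cell_bonds$cell_i[newly]] <- TRUE
    grounded[cell_bonds$cell_l[newly]] <- TRUE
    if (identical(before, grounded)) break
  }
  grounded
}

#' Effective adhesion parameters under cell-cell contact feedback
#'
#' Initiation of cell-cell contact remodels the cortex and boosts adhesion:
#' with contact, `gamma_cc` becomes `gamma_cc * (1 + 0.03 * N_sub)` (N_sub
#' the cell's current number of substrate bonds), `gamma_cs` becomes
#' `1.5 * gamma_cs` and the interaction range `d_cc` becomes `1.2 * d_cc`.
#' Without contact all three keep their base values.
#'
#' @param params a [model_params()] object.
#' @param has_cc_contact logical vector, one entry per cell (TRUE when the
#'   cell holds at least one attractive cell-cell bond).
#' @param N_sub integer vector of per-cell substrate-bond counts.
#' @param gamma_cc_base optional per-cell base `gamma_cc` (a dividing cell
#'   has 0); defaults to the global value.
#' @return data.frame with per-cell columns `gamma_cc_eff`, `gamma_cs_eff`,
#'   `d_cc_eff`.
#' @export
effective_adhesion_params <- function(params, has_cc_contact, N_sub,
                                      gamma_cc_base = NULL) {
  nc <- length(has_cc_contact)
  if (is.null(gamma_cc_base)) gamma_cc_base <- rep(params$gamma_cc, nc)
  stopifnot(length(N_sub) == nc, all(N_sub >= 0))
  data.frame(
    gamma_cc_eff = ifelse(has_cc_contact,
                          gamma_cc_base * (1 + params$fb_cc_per_bond * N_sub),
                          gamma_cc_base),
    gamma_cs_eff = ifelse(has_cc_contact,
                          params$fb_cs_factor * params$gamma_cs,
                          params$gamma_cs),
    d_cc_eff = ifelse(has_cc_contact,
                      params$fb_dcc_factor * params$d_cc,
                      params$d_cc)
  )
}

#' Spreading force magnitude under the three scaling models
#'
#' The active spreading force magnitude is `C_s` held constant, scaled
#' linearly with `gamma_cs / gamma_cs_ref`, or scaled nonlinearly as that
#' ratio to the power `spreading_exponent` (one fifth).
#'
#' @param mode `"constant"`, `"linear"` or `"nonlinear"` (defaults to the
#'   mode in `params`).
#' @param gamma_cs cell-substrate adhesion strength in force.
#' @param params a [model_params()] object.
#' @return Scalar force magnitude.
#' @examples
#' p <- model_params()
#' spreading_scale("nonlinear", 0.2 * p$gamma_cs_ref, p) / p$C_s # 0.2^0.2
#' @export
spreading_scale <- function(mode = NULL, gamma_cs = NULL, params) {
  if (is.null(mode)) mode <- params$spreading_mode
  if (is.null(gamma_cs)) gamma_cs <- params$gamma_cs
  if (gamma_cs < 0) stop("gamma_cs must be >= 0", call. = FALSE)
  if (mode == "constant") return(params$C_s)
  if (params$gamma_cs_ref <= 0)
    stop("gamma_cs_ref must be positive for scaled spreading modes",
         call. = FALSE)
  ratio <- gamma_cs / params$gamma_cs_ref
  switch(mode,
         linear = params$C_s * ratio,
         nonlinear = params$C_s * ratio^params$spreading_exponent,
         stop("unknown spreading mode: ", mode, call. = FALSE))
}

#' Active spreading forces on a cell
#'
#' Models lamellipodial protrusion: once at least `activation_fraction`
#' (10%) of a cell's nodes hold substrate bonds, a constant force of
#' magnitude `scale`, pointing 45 degrees outward and below horizontal, is
#' applied to the node immediately adjacent (along the polyline, outside the
#' bonded run) to the leftmost and rightmost substrate-bonded nodes.
#' Contact inhibition acts per side: a side whose contact flag is set
#' receives no spreading force, while spreading continues on the other side.
#'
#' @param cell an `epicell`.
#' @param cs_bonded logical per-node vector, TRUE if the node holds a
#'   substrate bond.
#' @param contact_left,contact_right per-side cell-cell contact flags.
#' @param params a [model_params()] object.
#' @param scale force magnitude (defaults to [spreading_scale()] under the
#'   configured mode).
#' @return n x 2 force matrix.
#' @export
spreading_forces <- function(cell, cs_bonded, contact_left = FALSE,
                             contact_right = FALSE, params, scale = NULL) {
  P <- node_matrix(cell)
  n <- nrow(P)
  F <- matrix(0, n, 2)
  nb <- sum(cs_bonded)
  if (nb == 0 || nb / n < params$activation_fraction) return(F)
  if (is.null(scale)) scale <- spreading_scale(params = params)
  idx <- which(cs_bonded)
  left <- idx[which.min(P[idx, 1])]
  right <- idx[which.max(P[idx, 1])]
  s2 <- sqrt(2) / 2
  if (!contact_left) {
    jl <- flank_outside(left, cs_bonded, P, side = "left")
    if (!is.na(jl)) F[jl, ] <- F[jl, ] + scale * c(-s2, -s2)
  }
  if (!contact_right) {
    jr <- flank_outside(right, cs_bonded, P, side = "right")
    if (!is.na(jr)) F[jr, ] <- F[jr, ] + scale * c(s2, -s2)
  }
  F
}

# neighbour of node j (along the closed polyline) that lies outside the
# bonded run, preferring the outward side in x
flank_outside <- function(j, cs_bonded, P, side) {
  n <- nrow(P)
  nbrs <- c(if (j == 1L) n else j - 1L, if (j == n) 1L else j + 1L)
  free <- nbrs[!cs_bonded[nbrs]]
  if (!length(free)) return(NA_integer_)
  if (length(free) == 1L) return(free)
  if (side == "left") free[which.min(P[free, 1])]
  else free[which.max(P[free, 1])]
}
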