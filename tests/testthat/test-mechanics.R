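params <- model_params()

test_that("internal forces are translation invariant (sum to zero)", {
  set.seed(21)
  for (k in 1:5) {
    cell <- fixture_cell(random_polygon(20), A0 = 1)
    F <- internal_forces(cell, params)
    expect_lt(max(abs(colSums(F))), 1e-10)
  }
})

test_that("internal forces match the finite-difference energy gradient", {
  set.seed(22)
  for (k in 1:20) {
    P <- random_polygon(12)
    cell <- fixture_cell(P, A0 = 1)
    F <- internal_forces(cell, params)
    G <- numerical_gradient_force(P, params$k_A, params$k_L, 1)
    expect_lt(max(abs(F - G)) / max(abs(G)), 1e-5)
  }
})

test_that("a cell at its preferred area with no cortical tension is force-free", {
  cell <- make_circular_cell(c(0, 0), 1, 64)
  cell$A0 <- polygon_area(cell)
  p0 <- model_params(k_L = 0)
  F <- internal_forces(cell, p0)
  expect_lt(max(abs(F)), 1e-12)
})

test_that("substrate bonds require proximity and mutual nearness", {
  sub <- make_substrate(-1, 1, 0.1)
  base <- make_circular_cell(c(0, 5), 0.5, 16) # far away, no bonds
  near <- base
  near$nodes[1, ] <- c(0.0, 0.05) # 0.05 above the substrate node at x=0
  bonds <- match_substrate_bonds(list(near), sub, params)
  expect_equal(nrow(bonds), 1L)
  expect_equal(bonds$node, 1L)
  expect_equal(bonds$dist, 0.05)
  far <- base
  far$nodes[1, ] <- c(0.0, 0.15) # beyond d_cs = 0.1
  expect_equal(nrow(match_substrate_bonds(list(far), sub, params)), 0L)
  # two cell nodes contending for one substrate node: closer one wins
  two <- base
  two$nodes[1, ] <- c(0.0, 0.05)
  two$nodes[2, ] <- c(0.01, 0.03)
  bonds2 <- match_substrate_bonds(list(two), sub, params)
  expect_equal(bonds2$node[bonds2$sub == which(sub$nodes[, 1] == 0)], 2L)
  # exclusivity: no substrate node bonded twice, no cell node bonded twice
  expect_false(any(duplicated(bonds2$sub)))
  expect_false(any(duplicated(bonds2[, c("cell", "node")])))
})

test_that("substrate adhesion force follows the linear spring law", {
  sub <- make_substrate(-1, 1, 0.1)
  cell <- make_circular_cell(c(0, 5), 0.5, 16)
  cell$nodes[1, ] <- c(0, params$l_cs) # at rest length: zero force
  b <- data.frame(cell = 1L, node = 1L, sub = which(sub$nodes[, 1] == 0),
                  dist = params$l_cs)
  F <- substrate_adhesion_forces(list(cell), sub, b, params)
  expect_equal(max(abs(F[[1]])), 0)
  # stretched spring: magnitude gamma_cs * (d - l_cs), pulling down
  cell$nodes[1, ] <- c(0, 0.1)
  b$dist <- 0.1
  F <- substrate_adhesion_forces(list(cell), sub, b, params)
  expect_equal(F[[1]][1, 2], -0.1 * (0.1 - 0.005), tolerance = 1e-12)
  expect_equal(F[[1]][1, 1], 0)
  expect_true(all(F[[1]][-1, ] == 0))
})

test_that("cell-cell bonds split into attractive and repulsive branches", {
  a <- make_circular_cell(c(0, 0), 0.5, 16)
  b <- make_circular_cell(c(5, 0), 0.5, 16)
  # place one node of each 0.1 apart
  a$nodes[1, ] <- c(0, 0); b$nodes[9, ] <- c(0.1, 0)
  bonds <- match_cell_bonds(list(a, b), params)
  expect_equal(nrow(bonds), 1L)
  expect_true(bonds$attractive)
  expect_equal(bonds$dist, 0.1)
  b$nodes[9, ] <- c(0.003, 0)
  bonds <- match_cell_bonds(list(a, b), params)
  expect_false(bonds$attractive[bonds$dist < 0.005])
  # nodes of the same cell never bond
  expect_equal(nrow(match_cell_bonds(list(a), params)), 0L)
})

test_that("cell adhesion forces have the printed magnitudes and are antisymmetric", {
  a <- make_circular_cell(c(0, 0), 0.5, 16)
  b <- make_circular_cell(c(5, 0), 0.5, 16)
  a$nodes[1, ] <- c(0, 0); b$nodes[9, ] <- c(0.1, 0)
  bonds <- match_cell_bonds(list(a, b), params)
  F <- cell_adhesion_forces(list(a, b), bonds, params)
  expect_equal(F[[1]][1, 1], 0.001 * 0.095, tolerance = 1e-12)
  expect_equal(F[[1]][1, ], -F[[2]][9, ])
  # at the rest length the force vanishes
  b$nodes[9, ] <- c(params$l_cc, 0)
  bonds <- match_cell_bonds(list(a, b), params)
  F <- cell_adhesion_forces(list(a, b), bonds, params)
  expect_equal(max(abs(F[[1]][1, ])), 0)
  # repulsive branch uses R_cc: 0.05 * |0.003 - 0.005| = 1e-4
  b$nodes[9, ] <- c(0.003, 0)
  bonds <- match_cell_bonds(list(a, b), params)
  F <- cell_adhesion_forces(list(a, b), bonds, params)
  expect_equal(F[[1]][1, 1], -0.05 * 0.002, tolerance = 1e-12)
  expect_equal(F[[1]][1, ], -F[[2]][9, ])
})

test_that("total force exchanged between two cells cancels", {
  set.seed(23)
  a <- fixture_cell(random_polygon(20, c(0.4, 0.6)))
  b <- fixture_cell(random_polygon(20, c(0.4, 0.6), center = c(1.0, 0)))
  bonds <- match_cell_bonds(list(a, b), params)
  expect_gt(nrow(bonds), 0)
  F <- cell_adhesion_forces(list(a, b), bonds, params)
  expect_lt(max(abs(colSums(F[[1]]) + colSums(F[[2]]))), 1e-12)
})

test_that("gravity acts only on cells without a path to the substrate", {
  sub <- make_substrate(-1, 1, 0.1)
  floating <- make_circular_cell(c(0, 3), 0.5, 16)
  F <- gravity_forces(list(floating), data.frame(cell = integer(0)),
                      match_cell_bonds(list(floating), params), params)
  expect_true(all(F[[1]][, 2] == -params$C_G))
  expect_true(all(F[[1]][, 1] == 0))
  # a cell with a substrate bond is exempt
  sb <- data.frame(cell = 1L, node = 1L, sub = 1L, dist = 0.05)
  F <- gravity_forces(list(floating), sb,
                      match_cell_bonds(list(floating), params), params)
  expect_true(all(F[[1]] == 0))
  # a floating cell bonded to a grounded cell is exempt too
  cb <- data.frame(cell_i = 1L, node_j = 1L, cell_l = 2L, node_k = 1L,
                   dist = 0.1, attractive = TRUE)
  F <- gravity_forces(list(floating, floating), sb, cb, params)
  expect_true(all(F[[2]] == 0))
})

test_that("contact feedback boosts adhesion as printed", {
  eff <- effective_adhesion_params(params, has_cc_contact = FALSE,
                                   N_sub = 10L)
  expect_equal(eff$gamma_cc_eff, params$gamma_cc)
  expect_equal(eff$gamma_cs_eff, params$gamma_cs)
  expect_equal(eff$d_cc_eff, params$d_cc)
  eff <- effective_adhesion_params(params, TRUE, 10L)
  expect_equal(eff$gamma_cc_eff, 1.3 * params$gamma_cc)
  expect_equal(eff$gamma_cs_eff, 1.5 * params$gamma_cs)
  expect_equal(eff$d_cc_eff, 0.192)
  eff <- effective_adhesion_params(params, TRUE, 0L)
  expect_equal(eff$gamma_cc_eff, params$gamma_cc)
  expect_equal(eff$gamma_cs_eff, 1.5 * params$gamma_cs)
})

test_that("spreading force scaling follows the three models", {
  expect_equal(spreading_scale("constant", 0.02, params), params$C_s)
  expect_equal(spreading_scale("linear", 0.05, params), 0.5 * params$C_s)
  expect_equal(spreading_scale("nonlinear", 0.02, params),
               0.2^0.2 * params$C_s, tolerance = 1e-12)
  expect_equal(spreading_scale("nonlinear", 0.02, params) / params$C_s,
               0.7248, tolerance = 1e-3)
  bad <- params
  bad$gamma_cs_ref <- 0
  expect_error(spreading_scale("linear", 0.05, bad), "gamma_cs_ref")
})

test_that("spreading needs 10% substrate contact and loads one flank per free side", {
  cell <- make_circular_cell(c(0, 0.5), 1, 100)
  bonded <- rep(FALSE, 100)
  bonded[1:5] <- TRUE # 5% of nodes: below activation
  expect_true(all(spreading_forces(cell, bonded, FALSE, FALSE, params) == 0))
  # bottom arc bonded (30%): exactly two loaded nodes, mirror-symmetric
  z <- cell$nodes[, 2]
  bonded <- rank(z) <= 30
  F <- spreading_forces(cell, bonded, FALSE, FALSE, params)
  loaded <- which(rowSums(abs(F)) > 0)
  expect_length(loaded, 2L)
  expect_equal(sort(F[loaded, 1]), params$C_s * sqrt(2) / 2 * c(-1, 1))
  expect_true(all(F[loaded, 2] == -params$C_s * sqrt(2) / 2))
  # left-side contact suppresses the left flank only
  Fl <- spreading_forces(cell, bonded, contact_left = TRUE,
                         contact_right = FALSE, params)
  loadedl <- which(rowSums(abs(Fl)) > 0)
  expect_length(loadedl, 1L)
  expect_gt(Fl[loadedl, 1], 0)
})
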