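test_that("remodeling bisects long edges and removes crowded nodes", {
  cell <- make_circular_cell(c(0, 0), 1, 16)
  ref <- cell$ref_spacing
  # skip two nodes of the regular polygon: the bridging chord spans three
  # steps (~2.85x ref), all other edges stay at ref
  long <- cell
  long$nodes <- cell$nodes[-c(2, 3), ]
  out <- remodel_cortex(long)
  expect_equal(nrow(out$nodes), nrow(long$nodes) + 1L)
  expect_equal(out$nodes[2, ], (cell$nodes[1, ] + cell$nodes[4, ]) / 2,
               ignore_attr = TRUE)
  # an extra node 0.3 ref after node 1 makes a short edge; the inserted
  # node is the endpoint closer to its other neighbour, so it is removed
  short <- cell
  extra <- cell$nodes[1, ] + (cell$nodes[2, ] - cell$nodes[1, ]) * 0.3
  short$nodes <- rbind(cell$nodes[1, , drop = FALSE], extra,
                       cell$nodes[-1, , drop = FALSE])
  out <- remodel_cortex(short)
  expect_equal(nrow(out$nodes), 16L)
  expect_equal(out$nodes, cell$nodes, ignore_attr = TRUE)
  # all edges in range: unchanged
  expect_identical(remodel_cortex(cell)$nodes, cell$nodes)
  expect_equal(remodel_cortex(cell)$ref_spacing, ref)
})

test_that("remodeling never drops a cell below eight nodes", {
  cell <- make_circular_cell(c(0, 0), 1e-4, 8) # tiny 8-gon
  squeezed <- cell
  squeezed$ref_spacing <- cell$ref_spacing * 10 # every edge now 'short'
  expect_warning(out <- remodel_cortex(squeezed), "8 nodes")
  expect_gte(nrow(out$nodes), 8L)
})

test_that("remodeling keeps edge lengths within bounds on static shapes", {
  set.seed(31)
  cell <- fixture_cell(random_polygon(40, c(0.4, 0.7)))
  for (k in 1:20) cell <- remodel_cortex(cell)
  P <- cell$nodes
  el <- sqrt(rowSums((P[c(2:nrow(P), 1), ] - P)^2))
  expect_true(all(el > 0.25 * cell$ref_spacing))
  expect_true(all(el < 2.5 * cell$ref_spacing))
})

test_that("the division program ramps the preferred area over the final hour", {
  cell <- make_circular_cell(c(0, 0), 1, 32, cycle_length = 4)
  p <- model_params()
  cell$age <- 2
  out <- update_division_program(cell, p)
  expect_equal(out$A0_target, 1)
  expect_true(out$gamma_cc_on)
  expect_false(out$division_due)
  cell$age <- 3.5
  out <- update_division_program(cell, p)
  expect_equal(out$A0_target, 1.5)
  expect_false(out$gamma_cc_on)
  cell$age <- 4
  out <- update_division_program(cell, p)
  expect_equal(out$A0_target, 2)
  expect_true(out$division_due)
  # non-cycling cells never change
  idle <- make_circular_cell(c(0, 0), 1, 32)
  idle$age <- 100
  out <- update_division_program(idle, p)
  expect_equal(out$A0_target, 1)
  expect_true(out$gamma_cc_on)
})

test_that("division conserves area and populates the cytokinetic plane", {
  parent <- make_circular_cell(c(0, 0), 2, 100)
  A <- polygon_area(parent)
  d <- divide_cell(parent)
  expect_length(d, 2L)
  areas <- vapply(d, polygon_area, numeric(1))
  expect_lt(abs(sum(areas) - A) / A, 0.02)
  expect_equal(areas[1], areas[2], tolerance = 0.05)
  # daughters reset
  expect_equal(d[[1]]$A0, parent$A0)
  expect_equal(d[[1]]$age, 0)
  # the chord (a vertical diameter ~1.6 long, ref spacing ~0.05) is
  # populated by repeated bisection: many more nodes than the half-arc
  expect_gt(nrow(d[[1]]$nodes), 50 + 15)
  P <- d[[1]]$nodes
  el <- sqrt(rowSums((P[c(2:nrow(P), 1), ] - P)^2))
  expect_true(all(el <= 2 * d[[1]]$ref_spacing + 1e-12))
})

test_that("a mirror-symmetric parent divides into mirror daughters", {
  n <- 100
  th <- 2 * pi * (seq_len(n) - 1) / n + pi / 2 # nodes exactly at top/bottom
  r <- sqrt(2 * 2 / (n * sin(2 * pi / n)))
  parent <- fixture_cell(cbind(r * cos(th), r * sin(th)), A0 = 1)
  d <- divide_cell(parent)
  m1 <- d[[1]]$nodes
  m2 <- d[[2]]$nodes
  expect_equal(nrow(m1), nrow(m2))
  # reflect daughter 2 in x and compare as point sets along the contour
  m2r <- cbind(-m2[, 1], m2[, 2])
  o1 <- m1[order(round(m1[, 2], 9), round(m1[, 1], 9)), ]
  o2 <- m2r[order(round(m2r[, 2], 9), round(m2r[, 1], 9)), ]
  expect_equal(o1, o2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("initial cell cycles are uniform on [0, 4] hours and reproducible", {
  x <- sample_initial_cycles(1e5, seed = 7)
  expect_true(all(x >= 0 & x <= 4))
  expect_equal(mean(x), 2, tolerance = 0.02)
  y <- sample_initial_cycles(1e5, seed = 7)
  expect_identical(x, y)
})
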