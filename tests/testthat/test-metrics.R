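test_that("connection fractions count bonded nodes", {
  cs <- rep(FALSE, 100); cs[1:30] <- TRUE
  cc <- rep(FALSE, 100)
  expect_equal(connection_fractions(cs, cc),
               c(f_cs = 0.30, f_cc = 0))
  expect_equal(connection_fractions(rep(FALSE, 10), rep(FALSE, 10)),
               c(f_cs = 0, f_cc = 0))
})

test_that("layer density follows the fixed Arb convention", {
  d <- layer_density(4, 4.78)
  expect_equal(d$linear_per_mm, 83.68201, tolerance = 1e-6)
  expect_equal(d$density_arb, 7.0, tolerance = 0.01)
  expect_equal(d$cells_per_mm2, 7002.28, tolerance = 1e-2)
  # square law: doubling cells at fixed span quadruples areal density
  expect_equal(layer_density(8, 4.78)$cells_per_mm2,
               4 * layer_density(4, 4.78)$cells_per_mm2)
  # undefined without substrate contact
  expect_true(is.na(layer_density(0, 4.78)$density_arb))
  expect_true(is.na(layer_density(4, NA)$density_arb))
})

test_that("apical:basal ratio matches closed forms", {
  # flat-bottomed half-disc: bonded bottom, free arc -> ratio ~ pi/2
  n_arc <- 101
  th <- seq(0, pi, length.out = n_arc)
  r <- 1
  arc <- cbind(r * cos(th), r * sin(th))
  bottom <- cbind(seq(-r + 0.02, r - 0.02, length.out = 99), 0)
  P <- rbind(cbind(rev(bottom[, 1]), 0), arc[-c(1, n_arc), ])
  P <- P[nrow(P):1, ] # counter-clockwise
  cell <- fixture_cell(P)
  cs <- abs(P[, 2]) < 1e-9
  cc <- rep(FALSE, nrow(P))
  ratio <- apical_basal_ratio(cell, cs, cc)
  expect_equal(ratio, pi / 2, tolerance = 0.05)
  # fully lateralized rectangle: top flat = bottom -> ratio 1
  w <- 1; h <- 0.6; k <- 40
  xs <- seq(0, w, length.out = k)
  zs <- seq(0, h, length.out = k)[-c(1, k)]
  R <- rbind(cbind(xs, 0), cbind(w, zs), cbind(rev(xs), h),
             cbind(0, rev(zs)))
  rc <- fixture_cell(R)
  cs <- R[, 2] == 0
  cc <- R[, 1] %in% c(0, w) & R[, 2] > 0 # side walls cell-cell bonded
  expect_equal(apical_basal_ratio(rc, cs, cc), 1, tolerance = 0.06)
  # undefined without substrate bonds
  expect_true(is.na(apical_basal_ratio(rc, rep(FALSE, nrow(R)), cc)))
})

test_that("architecture classification thresholds at 10% cell-cell contact", {
  expect_equal(classify_architecture(0.05), "Immature")
  expect_equal(classify_architecture(0.15), "Intermediate")
  expect_equal(classify_architecture(0.10), "Intermediate") # boundary
  # interior mask excludes colony edges
  expect_equal(classify_architecture(c(0.0, 0.15, 0.0),
                                     c(FALSE, TRUE, FALSE)),
               "Intermediate")
})

test_that("the shape index reproduces printed and closed-form values", {
  expect_equal(shape_index(0.84), 3.8678, tolerance = 1e-4)
  expect_equal(signif(shape_index(0.84), 3), 3.87)
  expect_equal(shape_index(1), sqrt(4 * pi))
  expect_equal(shape_index(pi / 4), 4)
  # internal consistency with the 2D vertex-model jamming point
  expect_equal(shape_index(4 * pi / 3.81^2), 3.81, tolerance = 1e-12)
  expect_error(shape_index(0), "circularity")
  expect_error(shape_index(1.2), "circularity")
})

test_that("transition density interpolates the first threshold crossing", {
  expect_equal(transition_density(c(2, 3, 4), c(0.04, 0.09, 0.13)), 3.25)
  expect_true(is.na(transition_density(c(2, 3, 4), c(0.01, 0.05, 0.09))))
  expect_equal(transition_density(c(2, 3, 4), c(0.04, 0.10, 0.13)), 3)
  expect_equal(transition_density(c(2, 3), c(0.2, 0.3)), 2) # already above
  expect_error(transition_density(c(3, 2), c(0.1, 0.2)), "sorted")
})

test_that("frame metrics agree with by-hand bond counting", {
  res <- run_scenario("two_cell_plating", steps = 1500, stride = 500)
  st <- epideform:::frame_state(res$trajectory,
                               res$trajectory$frames[[3]])
  m <- frame_metrics(st)
  bonds <- epideform:::state_bonds(st)
  for (i in 1:2) {
    n <- nrow(st$cells[[i]]$nodes)
    expect_equal(m$f_cs[i],
                 length(unique(bonds$sub_bonds$node[
                   bonds$sub_bonds$cell == i])) / n)
  }
  expect_equal(m$span[1],
               epideform:::occupied_span(st$cells, bonds$sub_bonds))
})
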