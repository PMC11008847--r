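test_that("circular cell construction round-trips the requested area", {
  cell <- make_circular_cell(c(0, 2), area = 1, n_nodes = 100)
  expect_equal(polygon_area(cell), 1, tolerance = 1e-9)
  expect_equal(nrow(cell$nodes), 100L)
  # counter-clockwise orientation: positive signed sum
  expect_gt(polygon_signed_sum(cell), 0)
  # reference spacing equals the closed-form regular-polygon value
  r <- sqrt(2 * 1 / (100 * sin(2 * pi / 100)))
  expect_equal(cell$ref_spacing, 2 * 100 * r * sin(pi / 100) / 100,
               tolerance = 1e-12)
  expect_equal(polygon_perimeter(cell), 2 * 100 * r * sin(pi / 100),
               tolerance = 1e-9)
})

test_that("degenerate construction arguments are rejected", {
  expect_error(make_circular_cell(c(0, 0), area = 0, n_nodes = 100),
               "positive")
  expect_error(make_circular_cell(c(0, 0), area = -1, n_nodes = 100),
               "positive")
  expect_error(make_circular_cell(c(0, 0), area = 1, n_nodes = 4),
               "at least 8")
})

test_that("substrate nodes are uniform on z = 0 and degenerate ranges fail", {
  sub <- make_substrate(0, 1, 0.1)
  expect_equal(nrow(sub$nodes), 11L)
  expect_equal(sub$nodes[, 1], seq(0, 1, by = 0.1), ignore_attr = TRUE)
  expect_true(all(sub$nodes[, 2] == 0))
  expect_error(make_substrate(0, 0, 0.1), "exceed")
  expect_error(make_substrate(0, 1, -0.1), "positive")
  # the conventional spacing equals a standard cell's node spacing
  cell <- make_circular_cell(c(0, 0), 1, 100)
  sub2 <- make_substrate(-2, 2, cell$ref_spacing)
  expect_equal(diff(sub2$nodes[1:2, 1]), cell$ref_spacing)
})

test_that("shoelace area matches closed forms and exposes orientation", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(polygon_area(sq), 1)
  expect_identical(polygon_area(sq[4:1, ]), 1)
  expect_lt(polygon_signed_sum(sq[4:1, ]), 0)
  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  expect_equal(polygon_area(hexa), 3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("area is invariant under reversal, translation and rotation", {
  set.seed(11)
  for (k in 1:5) {
    P <- random_polygon(15)
    A <- polygon_area(P)
    expect_equal(polygon_area(P[nrow(P):1, ]), A, tolerance = 1e-12)
    expect_equal(polygon_area(sweep(P, 2, c(3.2, -7.5))), A,
                 tolerance = 1e-12)
    th <- 0.83
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(polygon_area(P %*% R), A, tolerance = 1e-12)
  }
})

test_that("perimeter sums consecutive distances, coincident nodes add zero", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(polygon_perimeter(sq), 4)
  sq_dup <- rbind(c(0, 0), c(1, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_identical(polygon_perimeter(sq_dup), 4)
})

test_that("dimensional conversion is anchored at 100 um^2 per cell", {
  expect_equal(dimensional_units(strength = 0.1)$strength_N_per_m, 20)
  expect_equal(dimensional_units(length = 4.78)$length_um, 47.8)
  expect_equal(dimensional_units(area = 1)$area_um2, 100)
})

test_that("parameter validation enforces the model invariants", {
  expect_error(model_params(d_cc = 0.004), "d_cc")
  expect_error(model_params(dt = 0), "dt")
  expect_error(model_params(beta = -1), "beta")
  expect_error(model_params(gamma_cs = -0.1), ">= 0")
  p <- model_params(gamma_cc = 1e-5)
  expect_s3_class(p, "model_params")
  expect_equal(p$gamma_cc, 1e-5)
})
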