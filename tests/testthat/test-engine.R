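test_that("timestep-to-hours calibration is 750 steps per hour", {
  p <- model_params()
  expect_equal(steps_to_hours(750, p), 1)
  expect_equal(steps_to_hours(0, p), 0)
  expect_equal(steps_to_hours(18000, p), 24)
})

test_that("a force-free cell does not move", {
  p <- model_params(k_L = 0, C_G = 0)
  cell <- make_circular_cell(c(0, 2), 1, 32)
  cell$A0 <- polygon_area(cell) # exactly at the energy minimum
  sub <- make_substrate(100, 101, 0.05) # out of range
  st <- simulation_state(list(cell), sub, p)
  st2 <- epideform:::sim_step(st)
  expect_equal(st2$cells[[1]]$nodes, cell$nodes, tolerance = 1e-15)
})

test_that("a floating cell sinks rigidly at C_G * dt / beta per step", {
  p <- model_params(k_L = 0)
  cell <- make_circular_cell(c(0, 3), 1, 32)
  cell$A0 <- polygon_area(cell)
  sub <- make_substrate(-1, 1, 0.05)
  st <- simulation_state(list(cell), sub, p)
  st2 <- epideform:::sim_step(st)
  shift <- cell$nodes - st2$cells[[1]]$nodes
  expect_equal(shift[, 1], rep(0, 32), ignore_attr = TRUE)
  expect_equal(shift[, 2], rep(p$C_G * p$dt / p$beta, 32),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the reference step and the compiled engine agree", {
  cfg <- scenario_config("two_cell_plating", steps = 10, stride = 0)
  st <- epideform:::initial_state(cfg)$state
  st <- epideform:::advance_state(st, 900, stride = 0)$state
  stR <- st
  for (k in 1:3) stR <- epideform:::sim_step(stR)
  stC <- epideform:::advance_state(st, 3, stride = 0)$state
  for (i in 1:2)
    expect_equal(stR$cells[[i]]$nodes, stC$cells[[i]]$nodes,
                 tolerance = 1e-10)
  expect_identical(stR$contact, stC$contact)
  expect_identical(stR$nsub_prev, stC$nsub_prev)
  expect_equal(stR$cells[[1]]$age, stC$cells[[1]]$age, tolerance = 1e-12)
})

test_that("runs are deterministic and leave the substrate untouched", {
  a <- run_scenario("two_cell_plating", steps = 600, stride = 200, seed = 5)
  b <- run_scenario("two_cell_plating", steps = 600, stride = 200, seed = 5)
  expect_identical(a$trajectory$frames, b$trajectory$frames)
  expect_identical(a$trajectory$header$substrate,
                   b$trajectory$header$substrate)
  cfg <- scenario_config("two_cell_plating", steps = 1, stride = 0)
  sub0 <- epideform:::initial_state(cfg)$state$substrate
  expect_identical(a$trajectory$header$substrate, sub0)
})

test_that("node displacements per step stay below 0.05 length units", {
  res <- run_scenario("four_cell_confined", substrate_length = 5,
                      steps = 400, stride = 1)
  fr <- res$trajectory$frames
  # remodeling shifts node indices, so measure each node's distance to the
  # nearest node of the previous frame (a lower bound that equals the true
  # displacement whenever the discretization is unchanged)
  worst <- 0
  for (k in 2:length(fr)) {
    for (i in seq_along(fr[[k]]$nodes)) {
      a <- fr[[k - 1L]]$nodes[[i]]
      b <- fr[[k]]$nodes[[i]]
      d2 <- outer(b[, 1], a[, 1], "-")^2 + outer(b[, 2], a[, 2], "-")^2
      worst <- max(worst, sqrt(max(apply(d2, 1, min))))
    }
  }
  expect_lt(worst, 0.05)
})

test_that("the division scenario splits the central cell into two daughters", {
  # daughters share chord endpoints right after division; the coincident-
  # node bond warning is the documented degenerate-case behaviour
  res <- suppressWarnings(
    run_scenario("three_cell_division", seed = 3, stride = 100))
  nmax <- max(res$metrics$cell)
  expect_equal(nmax, 4L) # 3 initial cells, central divided once
  last <- res$metrics[res$metrics$step == max(res$metrics$step), ]
  # daughters (interior cells) are in contact; edges hold fewer contacts
  expect_true(all(last$f_cc[last$interior] > 0))
  expect_lt(mean(last$f_cc[!last$interior]),
            mean(last$f_cc[last$interior]))
})
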