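#' Create a simulation state
#'
#' Bundles cells, substrate and parameters together with the small amount of
#' per-cell history the dynamics carries between steps: the cell-cell
#' contact flags and substrate-bond counts of the previous step, which feed
#' the adhesion feedback when the next step's bonds are matched.
#'
#' @param cells list of `epicell` objects.
#' @param substrate an `episubstrate`.
#' @param params a [model_params()] object.
#' @return An object of class `"episim"`.
#' @export
simulation_state <- function(cells, substrate, params = model_params()) {
  nc <- length(cells)
  structure(list(
    cells = cells,
    substrate = substrate,
    params = params,
    step_index = 0L,
    contact = rep(FALSE, nc),
    contact_left = rep(FALSE, nc),
    contact_right = rep(FALSE, nc),
    nsub_prev = rep(0L, nc)
  ), class = "episim")
}

#' @export
print.episim <- function(x, ...) {
  cat(sprintf("<episim: %d cells, step %d (%.2f h)>\n", length(x$cells),
              x$step_index, steps_to_hours(x$step_index, x$params)))
  invisible(x)
}

#' Convert timesteps to culture hours
#'
#' The explicit-Euler timestep is calibrated against live imaging of cell
#' spreading: about 750 timesteps correspond to one hour in culture.
#'
#' @param n_steps number of timesteps (>= 0).
#' @param params a [model_params()] object (uses `steps_per_hour`).
#' @return Hours of culture-equivalent time.
#' @examples
#' steps_to_hours(18000, model_params()) # 24 h
#' @export
steps_to_hours <- function(n_steps, params = model_params()) {
  stopifnot(all(n_steps >= 0))
  n_steps / params$steps_per_hour
}

# Bond sets and contact flags for the current positions of `state`.
# Cell-cell matching uses the effective interaction range implied by the
# *previous* step's contact flags; the returned flags are the new ones.
state_bonds <- function(state) {
  params <- state$params
  nc <- length(state$cells)
  d_cc_eff <- ifelse(state$contact, params$fb_dcc_factor * params$d_cc,
                     params$d_cc)
  sub_bonds <- match_substrate_bonds(state$cells, state$substrate, params)
  cell_bonds <- match_cell_bonds(state$cells, params, d_cc_eff)
  has <- rep(FALSE, nc); left <- rep(FALSE, nc); right <- rep(FALSE, nc)
  if (nrow(cell_bonds)) {
    att <- cell_bonds[cell_bonds$attractive, , drop = FALSE]
    has[unique(c(att$cell_i, att$cell_l))] <- TRUE
    cx <- vapply(state$cells, function(cl) mean(node_matrix(cl)[, 1]),
                 numeric(1))
    for (b in seq_len(nrow(cell_bonds))) {
      i <- cell_bonds$cell_i[b]; l <- cell_bonds$cell_l[b]
      if (cx[l] < cx[i]) left[i] <- TRUE else right[i] <- TRUE
      if (cx[i] < cx[l]) left[l] <- TRUE else right[l] <- TRUE
    }
  }
  nsub <- tabulate(sub_bonds$cell, nbins = nc)
  list(sub_bonds = sub_bonds, cell_bonds = cell_bonds, has = has,
       left = left, right = right, nsub = nsub)
}

#' Advance a simulation state by one explicit-Euler timestep
#'
#' Reference implementation of the per-step orchestration, built from the
#' exported mechanics and remodeling operations. The order within a step is
#' fixed: divide any cell whose cycle has completed; remodel all cortices;
#' update division programs (growth ramp, adhesion cessation); recompute
#' bonds and contact flags (cell-cell matching range from the previous
#' step's contact state); compute effective adhesion parameters from the
#' new contact flags and the previous step's substrate-bond counts; sum the
#' five force contributions per node; move every cell node by
#' `dt * F / beta` (the substrate is fixed). [run_scenario()] uses the
#' compiled engine core, which implements exactly this step.
#'
#' @param state an `episim` state.
#' @return The advanced state.
#' @export
sim_step <- function(state) {
  params <- state$params
  # (0) divisions due from the previous step's ageing
  state <- perform_due_divisions(state)
  nc <- length(state$cells)
  # (1) cortical remodeling
  state$cells <- lapply(state$cells, remodel_cortex)
  # (2) division program (growth ramp, adhesion cessation)
  state$cells <- lapply(state$cells, update_division_program, params = params)
  # (3) bonds and contact flags
  bonds <- state_bonds(state)
  # (4) effective adhesion parameters (new contacts, previous N_sub)
  g_base <- vapply(state$cells, function(cl)
    if (isTRUE(cl$gamma_cc_on)) params$gamma_cc else 0, numeric(1))
  eff <- effective_adhesion_params(params, bonds$has, state$nsub_prev, g_base)
  # (5) forces
  sprd <- spreading_scale(params = params)
  total <- vector("list", nc)
  Fsub <- substrate_adhesion_forces(state$cells, state$substrate,
                                    bonds$sub_bonds, params,
                                    eff$gamma_cs_eff)
  Fcc <- cell_adhesion_forces(state$cells, bonds$cell_bonds, params,
                              eff$gamma_cc_eff)
  Fg <- gravity_forces(state$cells, bonds$sub_bonds, bonds$cell_bonds, params)
  for (i in seq_len(nc)) {
    cl <- state$cells[[i]]
    n <- nrow(cl$nodes)
    bonded <- rep(FALSE, n)
    sb <- bonds$sub_bonds[bonds$sub_bonds$cell == i, , drop = FALSE]
    bonded[sb$node] <- TRUE
    total[[i]] <- internal_forces(cl, params, A0 = cl$A0_target) +
      Fsub[[i]] + Fcc[[i]] + Fg[[i]] +
      spreading_forces(cl, bonded, bonds$left[i], bonds$right[i], params,
                       scale = sprd)
  }
  # (6) explicit Euler move and bookkeeping
  for (i in seq_len(nc)) {
    if (!all(is.finite(total[[i]])))
      stop("non-finite force at step ", state$step_index + 1L,
           " (cell ", i, ")")
    state$cells[[i]]$nodes <- state$cells[[i]]$nodes +
      params$dt * total[[i]] / params$beta
    state$cells[[i]]$age <- state$cells[[i]]$age + 1 / params$steps_per_hour
  }
  state$step_index <- state$step_index + 1L
  state$contact <- bonds$has
  state$contact_left <- bonds$left
  state$contact_right <- bonds$right
  state$nsub_prev <- bonds$nsub
  state
}

perform_due_divisions <- function(state) {
  due <- vapply(state$cells, function(cl)
    isTRUE(cl$dividing) && is.finite(cl$cycle_length) &&
      cl$age >= cl$cycle_length, logical(1))
  if (!any(due)) return(state)
  cells <- list(); contact <- logical(0); left <- logical(0)
  right <- logical(0); nsub <- integer(0)
  for (i in seq_along(state$cells)) {
    if (due[i]) {
      daughters <- divide_cell(state$cells[[i]])
      if (is.null(daughters)) { # degenerate axis: cell stays, stops cycling
        cl <- state$cells[[i]]
        cl$dividing <- FALSE
        daughters <- list(cl)
      }
      for (d in daughters) {
        cells[[length(cells) + 1L]] <- d
        contact <- c(contact, state$contact[i])
        left <- c(left, state$contact_left[i])
        right <- c(right, state$contact_right[i])
        nsub <- c(nsub, state$nsub_prev[i])
      }
    } else {
      cells[[length(cells) + 1L]] <- state$cells[[i]]
      contact <- c(contact, state$contact[i])
      left <- c(left, state$contact_left[i])
      right <- c(right, state$contact_right[i])
      nsub <- c(nsub, state$nsub_prev[i])
    }
  }
  state$cells <- cells
  state$contact <- contact
  state$contact_left <- left
  state$contact_right <- right
  state$nsub_prev <- nsub
  state
}

# Advance `state` by n_steps using the compiled core, recording frames every
# `stride` steps (counted on the global step index). Returns the state and
# appends frames to `frames`. Stops early (and performs the division in R)
# whenever a cell's cycle completes.
advance_state <- function(state, n_steps, stride = 50L, frames = list()) {
  params <- state$params
  done <- 0L
  while (done < n_steps) {
    state <- perform_due_divisions(state)
    res <- cpp_advance(
      lapply(state$cells, `[[`, "nodes"),
      vapply(state$cells, `[[`, numeric(1), "ref_spacing"),
      vapply(state$cells, `[[`, numeric(1), "A0"),
      vapply(state$cells, `[[`, numeric(1), "age"),
      vapply(state$cells, function(cl)
        if (is.finite(cl$cycle_length)) cl$cycle_length else -1, numeric(1)),
      vapply(state$cells, function(cl) isTRUE(cl$dividing), logical(1)),
      state$substrate$nodes,
      unclass(params),
      spreading_scale(params = params),
      as.integer(n_steps - done),
      as.integer(stride),
      as.integer(state$step_index),
      state$contact, state$contact_left, state$contact_right,
      as.integer(state$nsub_prev)
    )
    for (i in seq_along(state$cells)) {
      state$cells[[i]]$nodes <- res$cells[[i]]
      colnames(state$cells[[i]]$nodes) <- c("x", "z")
      state$cells[[i]]$age <- res$age[i]
    }
    state$contact <- res$contact
    state$contact_left <- res$contact_left
    state$contact_right <- res$contact_right
    state$nsub_prev <- as.integer(res$nsub)
    state$step_index <- state$step_index + res$steps_done
    done <- done + res$steps_done
    for (f in res$frames) {
      frames[[length(frames) + 1L]] <- list(
        step = f$step,
        nodes = f$nodes,
        age = f$age,
        contact = f$contact,
        contact_left = f$contact_left,
        contact_right = f$contact_right,
        nsub_prev = as.integer(f$nsub),
        gamma_cc_on = f$gamma_cc_on
      )
    }
    if (res$steps_done == 0L && done < n_steps) {
      # a division is due immediately; perform_due_divisions handles it on
      # the next loop iteration. Guard against no cell actually being due.
      if (!any(vapply(state$cells, function(cl)
        isTRUE(cl$dividing) && is.finite(cl$cycle_length) &&
          cl$age >= cl$cycle_length, logical(1))))
        stop("engine made no progress without a pending division")
    }
  }
  list(state = state, frames = frames)
}

#' Scenario configuration
#'
#' Builds the full configuration of a shipped scenario, with every field
#' resolved so the configuration alone reproduces the run. Scenarios:
#' \describe{
#'   \item{`single_cell_spreading`}{one cell dropped on a roomy substrate;
#'     with spreading it flattens, without (`spreading = FALSE`) it stays
#'     round.}
#'   \item{`two_cell_plating`}{two adjacent cells plated together; they
#'     spread, meet, and keep a minimal lateral contact while maximizing
#'     substrate coverage.}
#'   \item{`three_cell_division`}{three cells on a roomy substrate; cycle
#'     lengths are drawn from U[0, 4] h and the shortest is assigned to the
#'     central cell, so it divides before its neighbours. Only initial cells
#'     divide.}
#'   \item{`four_cell_confined`}{a four-cell colony confined by the
#'     substrate length for 24 h-equivalent; the densification workhorse.}
#'   \item{`isolated_cell`}{a single cell with no substrate in range and
#'     gravity off; relaxes to its analytic equilibrium shape.}
#' }
#'
#' @param scenario scenario name.
#' @param n_cells number of cells (scenario default if `NULL`).
#' @param substrate_length substrate extent in model length units (10 um
#'   each); density is controlled solely by this confinement.
#' @param steps number of timesteps (750 per culture hour).
#' @param stride frame-recording stride in steps.
#' @param seed RNG seed (used for cycle-length sampling).
#' @param n_nodes cortex nodes per initial cell.
#' @param params a [model_params()] object.
#' @param spreading logical; `FALSE` zeroes the active spreading force.
#' @param drop_gap initial gap between the cell bottom and the substrate.
#'   Plating scenarios drop cells from 0.4 model units; the confined colony
#'   is seeded essentially at the substrate (0.05) so that every cell
#'   engages it at once, as in a near-confluent seeding.
#' @param cycles optional explicit cycle lengths (hours) for the initial
#'   cells of `three_cell_division`.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("four_cell_confined",
                                         "single_cell_spreading",
                                         "two_cell_plating",
                                         "three_cell_division",
                                         "isolated_cell"),
                            n_cells = NULL, substrate_length = NULL,
                            steps = NULL, stride = 50L, seed = 1L,
                            n_nodes = 100L, params = model_params(),
                            spreading = TRUE, drop_gap = NULL,
                            cycles = NULL) {
  scenario <- match.arg(scenario)
  defaults <- switch(scenario,
    single_cell_spreading = list(n_cells = 1L, substrate_length = 6,
                                 steps = 9000L),
    two_cell_plating = list(n_cells = 2L, substrate_length = 8,
                            steps = 9000L),
    three_cell_division = list(n_cells = 3L, substrate_length = 14,
                               steps = NA_integer_, drop_gap = 0.05),
    four_cell_confined = list(n_cells = 4L, substrate_length = 4.78,
                              steps = 18000L, drop_gap = 0.05),
    isolated_cell = list(n_cells = 1L, substrate_length = 1, steps = 3000L)
  )
  cfg <- list(
    scenario = scenario,
    n_cells = if (is.null(n_cells)) defaults$n_cells else as.integer(n_cells),
    substrate_length = if (is.null(substrate_length))
      defaults$substrate_length else substrate_length,
    steps = if (is.null(steps)) defaults$steps else as.integer(steps),
    stride = as.integer(stride),
    seed = as.integer(seed),
    n_nodes = as.integer(n_nodes),
    params = params,
    spreading = isTRUE(spreading),
    drop_gap = if (is.null(drop_gap)) {
      if (is.null(defaults$drop_gap)) 0.4 else defaults$drop_gap
    } else drop_gap,
    cycles = cycles,
    version = "1"
  )
  if (cfg$steps < 1L && !is.na(cfg$steps))
    stop("steps must be >= 1", call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

# Initial placement: round cells in a row, dropped just above the substrate.
# Neighbouring cortices start just outside d_cc; if the substrate is too
# short for that, centres are compressed so all cells start above it.
initial_state <- function(cfg) {
  params <- cfg$params
  if (!cfg$spreading) {
    params$C_s <- 0
    cfg$params <- params
  }
  template <- make_circular_cell(c(0, 0), params$A0, cfg$n_nodes)
  r <- max(template$nodes[, 1])
  spacing_cells <- 2 * r + params$d_cc + 0.02
  L <- cfg$substrate_length
  if (cfg$scenario == "isolated_cell") {
    substrate <- make_substrate(100, 100 + L, template$ref_spacing)
    cells <- list(make_circular_cell(c(0, 2), params$A0, cfg$n_nodes))
    params$C_G <- 0
    cfg$params <- params
    st <- simulation_state(cells, substrate, params)
    return(list(state = st, cfg = cfg))
  }
  n <- cfg$n_cells
  if (cfg$scenario == "four_cell_confined" && n > 1L) {
    # confinement scenario: cells plated evenly over the available
    # substrate, as when varying density by limiting basal substrate
    spacing_cells <- (L - 2 * r) / (n - 1)
  } else if (n > 1L && (n - 1) * spacing_cells > L - 2 * r) {
    spacing_cells <- (L - 2 * r) / (n - 1)
  }
  centers_x <- (seq_len(n) - (n + 1) / 2) * spacing_cells
  z0 <- r + cfg$drop_gap
  cycles <- rep(NA_real_, n)
  if (cfg$scenario == "three_cell_division") {
    # cycle durations sampled U[0, 4] h, offset by a settling period so the
    # plated cells spread into an established layer before any division;
    # the shortest cycle goes to the central cell so it divides first, and
    # only the central cell divides in this scenario
    settle_h <- 6
    sampled <- if (!is.null(cfg$cycles)) sort(cfg$cycles)
               else sort(sample_initial_cycles(n, seed = cfg$seed))
    mid <- (n + 1L) %/% 2L
    cycles <- rep(NA_real_, n)
    cycles[mid] <- settle_h + sampled[1]
    if (is.na(cfg$steps)) {
      horizon <- cycles[mid] + 0.75
      cfg$steps <- as.integer(ceiling(horizon * params$steps_per_hour))
    }
  }
  cells <- lapply(seq_len(n), function(i)
    make_circular_cell(c(centers_x[i], z0), params$A0, cfg$n_nodes,
                       cycle_length = cycles[i]))
  substrate <- make_substrate(-L / 2, L / 2, template$ref_spacing)
  st <- simulation_state(cells, substrate, params)
  list(state = st, cfg = cfg)
}

#' Run a scenario
#'
#' Initializes the scenario, advances it with the compiled engine core
#' (performing any cell divisions as their cycles complete), records frames
#' at the configured stride, and computes per-frame layer metrics.
#' Deterministic given the configuration and seed.
#'
#' @param cfg a [scenario_config()] (or a scenario name, passed through).
#' @param ... passed to [scenario_config()] when `cfg` is a name.
#' @return A list of class `"episim_result"` with elements `config`
#'   (fully resolved), `trajectory` (see [write_trajectory()]) and
#'   `metrics` (data.frame, one row per cell per recorded frame; see
#'   [frame_metrics()]).
#' @examples
#' \donttest{
#' res <- run_scenario("single_cell_spreading", steps = 1500)
#' tail(res$metrics)
#' }
#' @export
run_scenario <- function(cfg, ...) {
  if (is.character(cfg)) cfg <- scenario_config(cfg, ...)
  if (!inherits(cfg, "scenario_config"))
    stop("cfg must be a scenario name or a scenario_config", call. = FALSE)
  set.seed(cfg$seed)
  ini <- initial_state(cfg)
  state <- ini$state
  cfg <- ini$cfg
  adv <- advance_state(state, cfg$steps, stride = cfg$stride)
  traj <- new_trajectory(cfg, state$substrate, adv$frames)
  metrics <- trajectory_metrics(traj)
  structure(list(config = cfg, trajectory = traj, metrics = metrics,
                 final_state = adv$state),
            class = "episim_result")
}

#' @export
print.episim_result <- function(x, ...) {
  cat(sprintf("<episim_result: %s, %d steps (%.1f h), %d frames>\n",
              x$config$scenario, x$config$steps,
              steps_to_hours(x$config$steps, x$config$params),
              length(x$trajectory$frames)))
  if (nrow(x$metrics)) {
    last <- x$metrics[x$metrics$step == max(x$metrics$step), ]
    cat(sprintf("final: density %.2f Arb, mean f_cs %.3f, mean f_cc %.3f, %s\n",
                last$density_arb[1], mean(last$f_cs), mean(last$f_cc),
                last$architecture[1]))
  }
  invisible(x)
}

# Rebuild an episim state for a recorded frame (positions after the frame's
# step, plus the contact/N_sub history carried into the next step) so that
# bonds and metrics can be recomputed exactly from a stored trajectory.
frame_state <- function(traj, frame) {
  params <- traj$header$params
  cells <- lapply(seq_along(frame$nodes), function(i) {
    nodes <- frame$nodes[[i]]
    colnames(nodes) <- c("x", "z")
    structure(list(nodes = nodes, A0 = params$A0,
                   ref_spacing = traj$header$ref_spacing,
                   cycle_length = NA_real_, age = frame$age[i],
                   dividing = FALSE,
                   gamma_cc_on = frame$gamma_cc_on[i]),
              class = "epicell")
  })
  st <- simulation_state(cells, traj$header$substrate, params)
  st$contact <- frame$contact
  st$contact_left <- frame$contact_left
  st$contact_right <- frame$contact_right
  st$nsub_prev <- frame$nsub_prev
  st$step_index <- frame$step
  st
}
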