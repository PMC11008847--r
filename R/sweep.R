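#' Default substrate lengths for a densification sweep
#'
#' Substrate lengths chosen so that a fully confined four-cell colony spans
#' target densities between about 1 and 9 Arb (`L = sqrt(160 / Arb)` for
#' four cells under the fixed density convention).
#'
#' @param n number of sweep points.
#' @param arb_range target density range in Arb.
#' @param n_cells cells in the colony.
#' @return Numeric vector of substrate lengths (model units), decreasing in
#'   density order (i.e. increasing density = decreasing length).
#' @export
default_sweep_lengths <- function(n = 12, arb_range = c(1, 9), n_cells = 4) {
  arb <- seq(arb_range[1], arb_range[2], length.out = n)
  # Arb = ((n_cells / (L * 0.01))^2) / 1000  =>  L = 100 n_cells / sqrt(1000 Arb)
  100 * n_cells / sqrt(1000 * arb)
}

#' Densification sweep
#'
#' Runs the four-cell confinement scenario once per substrate length and
#' summarizes the frames recorded over the final two culture hours of each
#' run: realized density, mean connection fractions (all cells, and
#' interior cells for classification), mean apical:basal ratio, and the
#' architecture label. Increasing density
#' is obtained purely by shrinking the available substrate.
#'
#' @param substrate_lengths substrate lengths to sweep (model units).
#' @param params a [model_params()] object (vary `gamma_cc`, `gamma_cs`,
#'   `spreading_mode` here to reproduce the adhesion sweeps).
#' @param steps timesteps per run (default 18000 = 24 h-equivalent).
#' @param seed RNG seed passed to each run.
#' @param n_cells colony size.
#' @param stride frame-recording stride (frames are only needed at the end,
#'   so a coarse stride keeps sweeps cheap).
#' @param n_nodes cortex nodes per cell.
#' @return data.frame, one row per substrate length, sorted by realized
#'   density: columns `substrate_length`, `span`, `density_arb`,
#'   `cells_per_mm2`, `f_cs`, `f_cc`, `f_cc_interior`, `apical_basal`,
#'   `architecture`.
#' @export
densification_sweep <- function(substrate_lengths = default_sweep_lengths(),
                                params = model_params(), steps = 18000L,
                                seed = 1L, n_cells = 4L, stride = 500L,
                                n_nodes = 100L) {
  rows <- lapply(substrate_lengths, function(L) {
    res <- run_scenario(scenario_config("four_cell_confined",
                                        n_cells = n_cells,
                                        substrate_length = L,
                                        steps = steps, stride = stride,
                                        seed = seed, n_nodes = n_nodes,
                                        params = params))
    s <- sweep_summary(res$metrics, params)
    cbind(data.frame(substrate_length = L), s)
  })
  out <- do.call(rbind, rows)
  out[order(out$density_arb), , drop = FALSE]
}

# Layer summary over the final two culture hours of a run (averaging the
# late frames damps the frame-to-frame flicker of discrete bond counts).
sweep_summary <- function(metrics, params, window_h = 2) {
  window_steps <- window_h * params$steps_per_hour
  late <- metrics[metrics$step > max(metrics$step) - window_steps, ]
  by_frame <- split(late, late$step)
  frame_stats <- lapply(by_frame, function(fr) {
    data.frame(
      span = fr$span[1],
      density_arb = fr$density_arb[1],
      cells_per_mm2 = fr$cells_per_mm2[1],
      f_cs = mean(fr$f_cs),
      f_cc = mean(fr$f_cc),
      f_cc_interior = mean(fr$f_cc[fr$interior]),
      apical_basal = mean(fr$apical_basal[fr$interior], na.rm = TRUE)
    )
  })
  agg <- do.call(rbind, frame_stats)
  out <- as.data.frame(lapply(agg, mean, na.rm = TRUE))
  out$architecture <- if (is.finite(out$f_cc_interior) &&
                          out$f_cc_interior >= params$cc_threshold)
    "Intermediate" else "Immature"
  out
}

#' Immature-to-Intermediate transition density of a sweep
#'
#' Convenience wrapper interpolating the first crossing of the cell-cell
#' connection threshold over a [densification_sweep()] table.
#'
#' @param sweep a [densification_sweep()] result.
#' @param cc_threshold crossing level (default 0.10).
#' @param scale `"arb"` or `"cells_per_mm2"`.
#' @return Crossing density (NA when never crossed).
#' @export
sweep_transition_density <- function(sweep, cc_threshold = 0.10,
                                     scale = c("arb", "cells_per_mm2")) {
  scale <- match.arg(scale)
  d <- if (scale == "arb") sweep$density_arb else sweep$cells_per_mm2
  ord <- order(d)
  transition_density(d[ord], sweep$f_cc_interior[ord], cc_threshold)
}

#' Density at which the apical:basal ratio turns over
#'
#' Locates where the interior-cell apical:basal surface-length ratio stops
#' increasing with density: the density of the maximum of the (3-point
#' moving-average smoothed) ratio profile across a densification sweep.
#'
#' @param sweep a [densification_sweep()] result.
#' @return Density in Arb at the trend turnover (NA if the ratio is still
#'   rising at the densest point).
#' @export
apical_basal_turnover <- function(sweep) {
  ord <- order(sweep$density_arb)
  d <- sweep$density_arb[ord]
  r <- sweep$apical_basal[ord]
  ok <- is.finite(r)
  d <- d[ok]; r <- r[ok]
  if (length(r) < 3) return(NA_real_)
  sm <- r
  for (i in 2:(length(r) - 1L)) sm[i] <- mean(r[(i - 1L):(i + 1L)])
  i <- which.max(sm)
  if (i == length(sm)) return(NA_real_)
  d[i]
}

#' Adhesion sweep at a fixed density
#'
#' Runs the four-cell scenario at one substrate length for a series of
#' cell-substrate adhesion strengths under a given spreading mode and
#' reports whether each reaches Intermediate classification; used to find
#' the weakest adhesion that still epithelializes at the highest density.
#'
#' @param gamma_cs_values substrate adhesion strengths (non-dimensional).
#' @param spreading_mode `"constant"`, `"linear"` or `"nonlinear"`.
#' @param substrate_length confinement (default: densest point of the
#'   standard sweep).
#' @param params base [model_params()].
#' @param steps,seed,stride,n_nodes as in [densification_sweep()].
#' @return data.frame with one row per adhesion value: `gamma_cs`,
#'   `gamma_cs_N_per_m`, `fraction_of_ref`, `f_cc_interior`,
#'   `architecture`.
#' @export
adhesion_sweep <- function(gamma_cs_values,
                           spreading_mode = c("nonlinear", "linear",
                                              "constant"),
                           substrate_length = min(default_sweep_lengths()),
                           params = model_params(), steps = 18000L,
                           seed = 1L, stride = 500L, n_nodes = 100L) {
  spreading_mode <- match.arg(spreading_mode)
  rows <- lapply(gamma_cs_values, function(g) {
    p <- params
    p$gamma_cs <- g
    p$spreading_mode <- spreading_mode
    res <- run_scenario(scenario_config("four_cell_confined",
                                        substrate_length = substrate_length,
                                        steps = steps, stride = stride,
                                        seed = seed, n_nodes = n_nodes,
                                        params = p))
    s <- sweep_summary(res$metrics, p)
    data.frame(
      gamma_cs = g,
      gamma_cs_N_per_m = dimensional_units(strength = g)$strength_N_per_m,
      fraction_of_ref = g / params$gamma_cs_ref,
      f_cc_interior = s$f_cc_interior,
      architecture = s$architecture
    )
  })
  do.call(rbind, rows)
}
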