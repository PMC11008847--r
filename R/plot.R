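#' Draw one trajectory frame
#'
#' Base-graphics rendering of a cross-section frame: the substrate as a
#' line on z = 0 and each cell cortex as a filled polygon.
#'
#' @param traj an `epitrajectory`.
#' @param frame frame index (default: last).
#' @param main plot title (default: scenario and time).
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the frame that was drawn.
#' @export
plot_frame <- function(traj, frame = length(traj$frames), main = NULL, ...) {
  f <- traj$frames[[frame]]
  sub <- traj$header$substrate$nodes
  xs <- range(c(sub[, 1], unlist(lapply(f$nodes, function(P) P[, 1]))))
  zs <- range(c(0, unlist(lapply(f$nodes, function(P) P[, 2]))))
  if (is.null(main))
    main <- sprintf("%s, t = %.2f h", traj$header$scenario,
                    steps_to_hours(f$step, traj$header$params))
  graphics::plot(NA, xlim = xs, ylim = zs + c(-0.1, 0.1), asp = 1,
                 xlab = "x (model units)", ylab = "z (model units)",
                 main = main, ...)
  graphics::lines(sub[, 1], sub[, 2], lwd = 3, col = "grey40")
  cols <- grDevices::hcl.colors(max(3, length(f$nodes)), "Set 2")
  for (i in seq_along(f$nodes)) {
    P <- f$nodes[[i]]
    graphics::polygon(P[, 1], P[, 2], col = grDevices::adjustcolor(
      cols[i], alpha.f = 0.5), border = cols[i])
  }
  invisible(f)
}

#' Render every frame of a trajectory to PNG images
#'
#' @param traj an `epitrajectory`.
#' @param out_dir output directory (created if needed).
#' @param width,height device size in pixels.
#' @return Character vector of the files written, invisibly.
#' @export
render_trajectory <- function(traj, out_dir, width = 800, height = 400) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(traj$frames))
  for (k in seq_along(traj$frames)) {
    files[k] <- file.path(out_dir, sprintf("frame_%05d.png",
                                           traj$frames[[k]]$step))
    grDevices::png(files[k], width = width, height = height)
    plot_frame(traj, k)
    grDevices::dev.off()
  }
  invisible(files)
}
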