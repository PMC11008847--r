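new_trajectory <- function(cfg, substrate, frames) {
  template <- make_circular_cell(c(0, 0), cfg$params$A0, cfg$n_nodes)
  structure(list(
    header = list(
      version = "1",
      scenario = cfg$scenario,
      seed = cfg$seed,
      params = cfg$params,
      config = cfg,
      substrate = substrate,
      ref_spacing = template$ref_spacing
    ),
    frames = frames
  ), class = "epitrajectory")
}

#' @export
print.epitrajectory <- function(x, ...) {
  cat(sprintf("<epitrajectory: %s, %d frames%s>\n", x$header$scenario,
              length(x$frames),
              if (length(x$frames))
                sprintf(", steps %d..%d", x$frames[[1]]$step,
                        x$frames[[length(x$frames)]]$step) else ""))
  invisible(x)
}

#' Write / read a trajectory
#'
#' Two interchangeable containers: `"csv"` writes a single plain-text file
#' with a JSON header line, a per-frame cell-state table and a node table
#' (comma separated, full `%.17g` precision); `"rds"` writes R's binary
#' serialization, which round-trips bit-exactly. The header carries the
#' fully resolved configuration, so the file alone reproduces the run.
#' `read_trajectory()` detects the format from the file contents.
#'
#' @param traj a trajectory (from [run_scenario()]`$trajectory`).
#' @param path output file path.
#' @param format `"csv"` or `"rds"`.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the trajectory object.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "epitrajectory"))
  if (format == "rds") {
    saveRDS(traj, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- traj$header
  hdr_json <- jsonlite::toJSON(list(
    version = hdr$version,
    scenario = hdr$scenario,
    seed = hdr$seed,
    params = unclass(hdr$params),
    config = unclass(hdr$config[setdiff(names(hdr$config), "params")]),
    substrate_x = hdr$substrate$nodes[, 1],
    substrate_spacing = hdr$substrate$spacing,
    ref_spacing = hdr$ref_spacing
  ), digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(c("#EPIDEFORM_TRAJECTORY v1", paste0("#HEADER ", hdr_json),
               "#CELLS"), con)
  writeLines("step,cell,n_nodes,age,contact,contact_left,contact_right,nsub_prev,gamma_cc_on",
             con)
  for (f in traj$frames) {
    nc <- length(f$nodes)
    writeLines(sprintf("%d,%d,%d,%.17g,%d,%d,%d,%d,%d",
                       f$step, seq_len(nc),
                       vapply(f$nodes, nrow, integer(1)), f$age,
                       as.integer(f$contact), as.integer(f$contact_left),
                       as.integer(f$contact_right), f$nsub_prev,
                       as.integer(f$gamma_cc_on)), con)
  }
  writeLines("#NODES", con)
  writeLines("step,cell,node,x,z", con)
  for (f in traj$frames) {
    for (i in seq_along(f$nodes)) {
      P <- f$nodes[[i]]
      writeLines(sprintf("%d,%d,%d,%.17g,%.17g", f$step, i,
                         seq_len(nrow(P)), P[, 1], P[, 2]), con)
    }
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path,
                               call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first)) stop("empty trajectory file: ", path, call. = FALSE)
  if (!startsWith(first, "#EPIDEFORM_TRAJECTORY")) {
    traj <- tryCatch(readRDS(path), error = function(e)
      stop("not a trajectory file: ", path, call. = FALSE))
    if (!inherits(traj, "epitrajectory"))
      stop("not a trajectory file: ", path, call. = FALSE)
    return(traj)
  }
  lines <- readLines(path, warn = FALSE)
  hline <- grep("^#HEADER ", lines)[1]
  if (is.na(hline)) stop("trajectory header missing in ", path,
                         call. = FALSE)
  hdr <- jsonlite::fromJSON(sub("^#HEADER ", "", lines[hline]),
                            simplifyVector = TRUE)
  cells_at <- which(lines == "#CELLS")[1]
  nodes_at <- which(lines == "#NODES")[1]
  if (is.na(cells_at) || is.na(nodes_at))
    stop("trajectory section markers missing in ", path, call. = FALSE)
  parse_csv <- function(lns) {
    if (length(lns) < 1L) return(NULL)
    utils::read.csv(text = lns, header = TRUE)
  }
  cells_df <- parse_csv(lines[(cells_at + 1L):(nodes_at - 1L)])
  nodes_df <- parse_csv(lines[(nodes_at + 1L):length(lines)])
  params <- do.call(model_params, hdr$params)
  cfg_fields <- hdr$config
  cfg <- scenario_config(cfg_fields$scenario,
                         n_cells = cfg_fields$n_cells,
                         substrate_length = cfg_fields$substrate_length,
                         steps = cfg_fields$steps,
                         stride = cfg_fields$stride,
                         seed = cfg_fields$seed,
                         n_nodes = cfg_fields$n_nodes,
                         params = params,
                         spreading = cfg_fields$spreading,
                         drop_gap = cfg_fields$drop_gap)
  substrate <- structure(list(
    nodes = cbind(x = hdr$substrate_x,
                  z = rep(0, length(hdr$substrate_x))),
    spacing = hdr$substrate_spacing
  ), class = "episubstrate")
  frames <- list()
  if (!is.null(cells_df) && nrow(cells_df)) {
    steps <- unique(cells_df$step)
    node_steps <- unique(nodes_df$step)
    for (s in steps) {
      cs <- cells_df[cells_df$step == s, , drop = FALSE]
      ns <- nodes_df[nodes_df$step == s, , drop = FALSE]
      nc <- nrow(cs)
      if (!nrow(ns))
        stop("trajectory truncated; last valid frame before step ", s,
             call. = FALSE)
      nodes <- vector("list", nc)
      for (i in seq_len(nc)) {
        ni <- ns[ns$cell == i, , drop = FALSE]
        if (nrow(ni) != cs$n_nodes[i] || !nrow(ni) ||
            max(ni$node) != nrow(ni))
          stop("trajectory truncated; last valid frame before step ", s,
               call. = FALSE)
        nodes[[i]] <- cbind(x = ni$x, z = ni$z)
      }
      frames[[length(frames) + 1L]] <- list(
        step = cs$step[1],
        nodes = nodes,
        age = cs$age,
        contact = as.logical(cs$contact),
        contact_left = as.logical(cs$contact_left),
        contact_right = as.logical(cs$contact_right),
        nsub_prev = as.integer(cs$nsub_prev),
        gamma_cc_on = as.logical(cs$gamma_cc_on)
      )
    }
    extra <- setdiff(node_steps, steps)
    if (length(extra))
      stop("trajectory has node rows for unlisted frames; file corrupt",
           call. = FALSE)
  }
  traj <- new_trajectory(cfg, substrate, frames)
  traj$header$params <- params
  traj
}

#' Load a scenario configuration from a YAML file
#'
#' The file may specify any subset of the scenario fields (`scenario`,
#' `n_cells`, `substrate_length`, `steps`, `stride`, `seed`, `n_nodes`,
#' `spreading`, `drop_gap`, `cycles`) and a nested `params` block with any
#' [model_params()] argument (e.g. `gamma_cc: 1.0e-5` for the weak-adhesion
#' sweeps). Unspecified fields take the standard non-dimensional defaults.
#' Unknown keys raise an error listing them; non-numeric values for numeric
#' fields raise a parse error naming the key.
#'
#' @param path YAML file path.
#' @return A fully resolved [scenario_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("config parse error in ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  known <- c("scenario", "n_cells", "substrate_length", "steps", "stride",
             "seed", "n_nodes", "spreading", "drop_gap", "cycles", "params")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pargs <- raw$params
  if (!is.null(pargs)) {
    if (!is.list(pargs)) stop("'params' must be a mapping", call. = FALSE)
    pknown <- names(formals(model_params))
    punknown <- setdiff(names(pargs), setdiff(pknown, "..."))
    if (length(punknown))
      stop("unknown params keys: ", paste(punknown, collapse = ", "),
           call. = FALSE)
    for (nm in setdiff(names(pargs), "spreading_mode"))
      if (!is.numeric(pargs[[nm]]))
        stop("config value for params.", nm, " is not numeric",
             call. = FALSE)
  }
  numeric_fields <- c("n_cells", "substrate_length", "steps", "stride",
                      "seed", "n_nodes", "drop_gap", "cycles")
  for (nm in intersect(names(raw), numeric_fields))
    if (!is.numeric(raw[[nm]]))
      stop("config value for ", nm, " is not numeric", call. = FALSE)
  params <- if (is.null(pargs)) model_params()
            else do.call(model_params, pargs)
  scenario_config(
    scenario = if (is.null(raw$scenario)) "four_cell_confined"
               else raw$scenario,
    n_cells = raw$n_cells,
    substrate_length = raw$substrate_length,
    steps = raw$steps,
    stride = if (is.null(raw$stride)) 50L else raw$stride,
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    n_nodes = if (is.null(raw$n_nodes)) 100L else raw$n_nodes,
    params = params,
    spreading = if (is.null(raw$spreading)) TRUE else raw$spreading,
    drop_gap = if (is.null(raw$drop_gap)) 0.4 else raw$drop_gap,
    cycles = raw$cycles
  )
}

#' Write a metrics table as CSV
#'
#' Comma-separated, header row, `.` decimal separator.
#'
#' @param metrics data.frame (e.g. from [run_scenario()] or
#'   [densification_sweep()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}
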