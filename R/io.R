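## Plain-text exporters and parameter serialization.

#' Export a chain configuration as XYZ
#'
#' One record per bead; the comment line carries the simulated time.
#'
#' @param state a [chain_state()].
#' @param path output path.
#' @param element element symbol used for every bead.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, element = "C") {
  stopifnot(inherits(state, "chain_state"))
  pos <- state$positions
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(nrow(pos)), sprintf("t = %.6e s", state$time)), con)
  writeLines(sprintf("%s %.6f %.6f %.6f", element, pos[, 1], pos[, 2], pos[, 3]), con)
  invisible(path)
}

#' Export a chain configuration as CSV
#'
#' @param state a [chain_state()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(state, path) {
  stopifnot(inherits(state, "chain_state"))
  df <- data.frame(bead_index = seq_len(nrow(state$positions)),
                   x_nm = state$positions[, 1], y_nm = state$positions[, 2],
                   z_nm = state$positions[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a centre-of-mass track as CSV
#'
#' @param trajectory a [run_simulation()] trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_com_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- data.frame(time_s = trajectory$times, x_nm = trajectory$com[, 1],
                   y_nm = trajectory$com[, 2], z_nm = trajectory$com[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize chain parameters to YAML
#'
#' Writes every field of a [chain_parameters()] object under keys matching the
#' field names; [read_chain_parameters()] restores an equal object.
#'
#' @param params a [chain_parameters()] object.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_chain_parameters <- function(params, path) {
  stopifnot(inherits(params, "chain_parameters"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_chain_parameters
#' @export
read_chain_parameters <- function(path) {
  do.call(chain_parameters, yaml::read_yaml(path))
}

#' Export a potential grid as legacy VTK structured points
#'
#' Text-format VTK file with the potential (masked nodes written as 0) for
#' visualization.
#'
#' @param grid a solved [potential_grid].
#' @param path output path (.vtk).
#' @return `path`, invisibly.
#' @export
write_grid_vtk <- function(grid, path) {
  stopifnot(inherits(grid, "potential_grid"), grid$solved)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "electrostatic potential (V)",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$dims[1], grid$dims[2], grid$dims[3]),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$spacing, grid$spacing, grid$spacing),
               sprintf("POINT_DATA %d", prod(grid$dims)),
               "SCALARS phi double 1", "LOOKUP_TABLE default"), con)
  vals <- as.numeric(grid$values)
  vals[as.integer(grid$mask) == 0L] <- 0
  writeLines(format(vals, digits = 9, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}

#' Save / load simulation artifacts
#'
#' Binary round-trip of grids and trajectories for reuse between runs
#' (RDS serialization).
#'
#' @param object a [potential_grid] or [run_simulation()] trajectory.
#' @param path file path.
#' @return `path` / the restored object.
#' @export
save_artifact <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_artifact
#' @export
read_artifact <- function(path) readRDS(path)
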