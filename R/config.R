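## Run configuration, presets and fixture generation.

.chain_defaults <- list(N = 400, N_nt = 48000, r_nt = 0.43, alpha = 0.847,
                        sigma = 5, omega_kT = 1, D_target = 2.21e-12,
                        mu_target = 2.84e-8, T = 300)

.geometry_defaults <- list(reservoir_dims = c(2500, 4000, 500),
                           channel_length = 2200, channel_width = 500,
                           channel_height = 30, pore_length = 200,
                           pore_width = 30, pore_height = 30,
                           pore_start_x = 1000,
                           electrode_potentials = c(-0.4, 0.4),
                           electrode_offset = 2500)

.integrator_defaults <- list(dt = 1e-11, n_steps = 1000L, seed = 1L,
                             output_stride = 100L, snapshot_stride = 0L,
                             temperature = 300)

.config_schema <- list(
  mode = c("free", "uniform_field", "translocation"),
  chain = names(.chain_defaults),
  geometry = names(.geometry_defaults),
  integrator = names(.integrator_defaults),
  field_strength = NULL, spacing = NULL, paths = c("output"), log_level = NULL)

#' Geometry presets
#'
#' Ready-made [channel_geometry()] objects.
#' \describe{
#'   \item{paper_30x30 / paper_40x40 / paper_50x50}{the tabulated study
#'     geometries: 2200 x 500 x h nm channel with a 200 nm long pore of
#'     cross-section w x h at x = 1000-1200 nm, 2.5 x 4.0 x 0.5 um reservoirs
#'     and electrodes at -0.4 / +0.4 V, 2.5 um from the entrances.}
#'   \item{paper_20x20}{the failure-to-enter scenario: the field outside a
#'     20 x 20 nm pore is too weak to pull the coil in.}
#'   \item{reduced_30x30 / reduced_40x40 / reduced_50x50}{shortened
#'     channel/reservoirs (1000 nm channel, pore at 400-600 nm) for
#'     desk-scale field studies; same pore cross-sections.}
#'   \item{scaled}{the 10x scaled-down translocation system (220 x 50 x 15 nm
#'     channel, 20 nm long 15 x 15 nm pore at 100-120 nm) matched to the
#'     scaled chain preset.}
#' }
#'
#' @param name preset name.
#' @return a [channel_geometry()].
#' @export
preset_geometry <- function(name = c("paper_30x30", "paper_40x40", "paper_50x50",
                                     "paper_20x20", "reduced_30x30",
                                     "reduced_40x40", "reduced_50x50", "scaled")) {
  name <- match.arg(name)
  if (grepl("^paper", name)) {
    w <- as.numeric(sub("paper_(\\d+)x\\d+", "\\1", name))
    channel_geometry(reservoir_dims = c(2500, 4000, 500), channel_length = 2200,
                     channel_width = 500, channel_height = w, pore_length = 200,
                     pore_width = w, pore_height = w, pore_start_x = 1000,
                     electrode_potentials = c(-0.4, 0.4), electrode_offset = 2500)
  } else if (grepl("^reduced", name)) {
    w <- as.numeric(sub("reduced_(\\d+)x\\d+", "\\1", name))
    channel_geometry(reservoir_dims = c(600, 2000, 400), channel_length = 1000,
                     channel_width = 500, channel_height = w, pore_length = 200,
                     pore_width = w, pore_height = w, pore_start_x = 400,
                     electrode_potentials = c(-0.4, 0.4), electrode_offset = 600)
  } else {
    channel_geometry(reservoir_dims = c(250, 400, 50), channel_length = 220,
                     channel_width = 50, channel_height = 15, pore_length = 20,
                     pore_width = 15, pore_height = 15, pore_start_x = 100,
                     electrode_potentials = c(-0.4, 0.4), electrode_offset = 250)
  }
}

#' Chain presets
#'
#' `"paper"` is the 48 knt chain on 400 beads (r_eq = 43.7 nm). `"scaled"` is
#' the 10x scaled-down chain used for desk-scale translocation studies: 480 nt
#' on 40 beads (12 nt per bead, r_eq = 4.37 nm) with the same per-bead
#' friction and charge as the full chain (D_target scales as 1/N at fixed
#' zeta).
#'
#' @param name preset name.
#' @return a [chain_parameters()] object.
#' @export
preset_chain <- function(name = c("paper", "scaled")) {
  name <- match.arg(name)
  if (name == "paper") do.call(derive_parameters, .chain_defaults)
  else derive_parameters(N = 40, N_nt = 480, r_nt = 0.43, alpha = 0.847,
                         sigma = 5, omega_kT = 1, D_target = 2.21e-12 * 10,
                         mu_target = 2.84e-8, T = 300)
}

#' Load a run configuration
#'
#' Reads a YAML run configuration, validates it against the schema (unknown
#' keys are rejected, listing every offending key), fills in defaults, and
#' returns a fully resolved `run_config`.
#'
#' @param path YAML file path.
#' @return object of class `run_config` with `mode`, `chain`
#'   ([chain_parameters()]), `geometry` ([channel_geometry()]), `integrator`
#'   ([integrator_config()]), and mode-specific extras.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)))
    stop("load_config: empty or malformed config; required keys: mode, chain, geometry, integrator")
  ## YAML 1.1 parses a bare `N` key as the boolean FALSE; restore it
  if (!is.null(raw$chain) && "FALSE" %in% names(raw$chain))
    names(raw$chain)[names(raw$chain) == "FALSE"] <- "N"
  bad <- setdiff(names(raw), names(.config_schema))
  for (sec in c("chain", "geometry", "integrator", "paths")) {
    if (!is.null(raw[[sec]])) {
      extra <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
      if (length(extra)) bad <- c(bad, paste0(sec, ".", extra))
    }
  }
  if (length(bad))
    stop("load_config: unknown key(s): ", paste(bad, collapse = ", "))
  if (is.null(raw$mode) || !raw$mode %in% .config_schema$mode)
    stop("load_config: 'mode' must be one of ",
         paste(.config_schema$mode, collapse = ", "))
  if (raw$mode == "uniform_field" && is.null(raw$field_strength))
    stop("load_config: uniform_field mode requires 'field_strength' (V/m)")
  ## YAML needs a signed exponent (1.0e+6) for scientific notation; tolerate
  ## the common unsigned form by coercing numeric scalars
  for (f in c("field_strength", "spacing"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.numeric(raw[[f]])
  chain_args <- modifyList(.chain_defaults, as.list(raw$chain %||% list()))
  geo_args <- modifyList(.geometry_defaults, as.list(raw$geometry %||% list()))
  int_args <- modifyList(.integrator_defaults, as.list(raw$integrator %||% list()))
  structure(list(mode = raw$mode,
                 chain = do.call(derive_parameters, chain_args),
                 geometry = do.call(channel_geometry, geo_args),
                 integrator = do.call(integrator_config, int_args),
                 field_strength = raw$field_strength,
                 spacing = raw$spacing %||% 10,
                 paths = raw$paths, log_level = raw$log_level %||% "info",
                 raw = list(mode = raw$mode, chain = chain_args,
                            geometry = geo_args, integrator = int_args,
                            field_strength = raw$field_strength,
                            spacing = raw$spacing %||% 10)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration
#'
#' Writes the fully resolved configuration back to YAML; `load_config()` on
#' the result reproduces an equal configuration (round-trip idempotence).
#'
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- config$raw
  out$integrator$n_steps <- as.integer(out$integrator$n_steps)
  out <- Filter(Negate(is.null), out)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: mode = %s, N = %d beads, seed = %d, %d steps\n",
              x$mode, x$chain$N, x$integrator$seed, x$integrator$n_steps))
  invisible(x)
}

#' Deterministic test fixtures
#'
#' Generates the small synthetic objects the analysis operations are tested
#' against, reproducibly for a fixed seed.
#' \describe{
#'   \item{toy_chain}{a 5-40 bead chain (scaled parameter set) as a
#'     [chain_state()].}
#'   \item{toy_geometry}{the 10x scaled-down channel geometry.}
#'   \item{synthetic_brownian}{`size` exact Brownian centre-of-mass tracks
#'     with diffusion coefficient `D` (trajectory objects).}
#'   \item{synthetic_drift}{`size` drift-plus-diffusion tracks with drift
#'     velocity `v` along x.}
#'   \item{occupancy_mixture}{an integer occupancy series drawn from a
#'     mixture of the unfolded baseline `b` and the 1-fold level `2 b` with
#'     the given weights.}
#' }
#'
#' @param kind fixture kind.
#' @param seed RNG seed.
#' @param size kind-specific size (bead count, number of tracks, or frames).
#' @param path optional path; the fixture is also saved there as RDS.
#' @param D,v,n_frames,frame_dt,baseline,weights fixture parameters (see
#'   details above).
#' @return the fixture object (invisibly also written to `path` if given).
#' @export
make_fixture <- function(kind = c("toy_chain", "toy_geometry", "synthetic_brownian",
                                  "synthetic_drift", "occupancy_mixture"),
                         seed = 1, size = 10, path = NULL, D = 2.21e-12,
                         v = 2.84e-2, n_frames = 201, frame_dt = 1e-8,
                         baseline = 5L, weights = c(0.7, 0.3)) {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("make_fixture: unknown kind '", kind[1], "'"))
  obj <- switch(kind,
    toy_chain = {
      n <- max(5L, min(40L, as.integer(size)))
      p <- derive_parameters(N = n, N_nt = 12 * n, r_nt = 0.43, alpha = 0.847,
                             sigma = 5, D_target = 2.21e-12 * 400 / n)
      initialize_chain(p, seed = seed)
    },
    toy_geometry = preset_geometry("scaled"),
    synthetic_brownian = .brownian_tracks(seed, size, D, 0, n_frames, frame_dt),
    synthetic_drift = .brownian_tracks(seed, size, D, v, n_frames, frame_dt),
    occupancy_mixture = with_seed(seed, {
      lv <- sample(c(baseline, 2L * baseline), size, replace = TRUE,
                   prob = weights)
      structure(list(times = (seq_len(size) - 1) * frame_dt, n_pore = lv,
                     pore_interval = c(0, 200), entered = TRUE),
                class = "occupancy_series")
    }))
  if (!is.null(path)) saveRDS(obj, path)
  invisible(obj)
}

## exact-distribution Brownian/drift com tracks as trajectory objects
.brownian_tracks <- function(seed, n_tracks, D, v, n_frames, frame_dt) {
  with_seed(seed, lapply(seq_len(n_tracks), function(i) {
    steps <- matrix(rnorm(3 * (n_frames - 1), 0, sqrt(2 * D * frame_dt)),
                    n_frames - 1, 3)
    steps[, 1] <- steps[, 1] + v * frame_dt
    com <- rbind(0, apply(steps, 2, cumsum)) * 1e9  # nm
    structure(list(times = (seq_len(n_frames) - 1) * frame_dt, com = com,
                   snapshots = NULL, mode = if (v == 0) "free" else "uniform",
                   seed = seed + i, dt = frame_dt, output_stride = 1L,
                   snapshot_stride = 0L),
              class = "trajectory")
  }))
}
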