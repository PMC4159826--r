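#' Integrator settings
#'
#' Settings of the overdamped Euler-Langevin integrator. The default time step
#' of 10 ps is stable for the default chain parameters (bond relaxation time
#' zeta/k is tens of steps).
#'
#' @param dt time step (s).
#' @param n_steps number of steps (>= 1).
#' @param seed RNG seed; every stochastic run is fully reproducible for a
#'   fixed seed.
#' @param output_stride record the centre of mass every this many steps.
#' @param snapshot_stride record full bead snapshots every this many steps
#'   (0 = none).
#' @param temperature bath temperature (K); 0 switches the thermal force off.
#' @return an object of class `integrator_config`.
#' @export
integrator_config <- function(dt = 1e-11, n_steps, seed, output_stride = 100,
                              snapshot_stride = 0, temperature = 300) {
  if (missing(seed)) stop("integrator_config: a seed is required")
  stopifnot(dt > 0, n_steps >= 1, output_stride >= 1, snapshot_stride >= 0,
            temperature >= 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed),
                 output_stride = as.integer(output_stride),
                 snapshot_stride = as.integer(snapshot_stride),
                 temperature = temperature),
            class = "integrator_config")
}

#' Thermal random forces
#'
#' One draw of the discretized fluctuation-dissipation random force: each
#' component is independent Gaussian with zero mean and variance
#' `2 * zeta * kB * T / dt` (the Ito discretization of the delta-correlated
#' noise correlator), uncorrelated across beads and components.
#'
#' @param params a [chain_parameters()] object (supplies zeta and T).
#' @param dt time step (s).
#' @param n number of beads (default `params$N`).
#' @return n x 3 matrix of forces (N).
#' @export
random_forces <- function(params, dt, n = params$N) {
  stopifnot(inherits(params, "chain_parameters"), dt > 0)
  sdv <- if (params$T > 0) sqrt(2 * params$zeta * .kB * params$T / dt) else 0
  matrix(rnorm(3 * n, 0, sdv), n, 3)
}

#' Wall repulsion forces
#'
#' WCA repulsion from every wall face of the channel/pore closer than the
#' cutoff, acting along the inward normal computed from the perpendicular
#' distance (mirror symmetry: no tangential component). Beads in the
#' reservoirs only feel the membrane end faces around the channel opening;
#' reservoir side walls are treated as far away.
#'
#' @param state a [chain_state()].
#' @param geometry a [channel_geometry()].
#' @param params a [chain_parameters()] object.
#' @return N x 3 matrix of forces (N).
#' @export
wall_forces <- function(state, geometry, params) {
  stopifnot(inherits(state, "chain_state"), inherits(geometry, "channel_geometry"),
            inherits(params, "chain_parameters"))
  wall_forces_cpp(state$positions, .geom_vec(geometry), params$sigma, params$omega,
                  params$cutoff)
}

#' One overdamped Euler step
#'
#' Displaces each bead by `force / zeta * dt` (no inertial term) and advances
#' the clock by dt. Forces must have been evaluated at the current state.
#'
#' @param state a [chain_state()].
#' @param total_force N x 3 matrix of forces (N).
#' @param params a [chain_parameters()] object.
#' @param dt time step (s).
#' @return the advanced [chain_state()].
#' @export
step <- function(state, total_force, params, dt) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "chain_parameters"))
  disp_nm <- total_force / params$zeta * dt * 1e9
  if (!all(is.finite(disp_nm)))
    stop("step: non-finite displacement (numerical blowup)")
  chain_state(state$positions + disp_nm, time = state$time + dt)
}

#' Run an overdamped Langevin simulation
#'
#' Advances the chain with the Euler scheme, composing harmonic bond forces,
#' WCA excluded volume (cell-list), wall repulsion, the electric force and the
#' thermal random force at every step. Three modes are supported:
#' \describe{
#'   \item{free}{no walls, no field (free-solution diffusion).}
#'   \item{uniform}{no walls, constant electric field `field$E` (V/m,
#'     3-vector); the force on each bead is `Q * E`.}
#'   \item{translocation}{full channel geometry with the solved nonuniform
#'     field of a [potential_grid].}
#' }
#' Runs are bit-reproducible for a fixed seed. If a step would carry a bead
#' through a wall despite the repulsion, the position is mirror-reflected
#' across the crossed face (counted in `n_reflected`).
#'
#' @param initial a [chain_state()] (see [initialize_chain()] and
#'   [place_at_entrance()]).
#' @param params a [chain_parameters()] object.
#' @param config an [integrator_config()].
#' @param geometry a [channel_geometry()] (translocation mode).
#' @param field `NULL` (free), `list(E = c(Ex, Ey, Ez))` (uniform, V/m), or a
#'   solved [potential_grid] (translocation).
#' @param tether_k optional harmonic tether (N/m) binding each bead to its
#'   initial position; used for fluctuation-dissipation validation.
#' @return an object of class `trajectory`: recorded `times` (s), `com`
#'   (M x 3, nm), optional `snapshots` (list of N x 3 matrices), the final
#'   state, mode and provenance metadata.
#' @export
run_simulation <- function(initial, params, config, geometry = NULL, field = NULL,
                           tether_k = 0) {
  stopifnot(inherits(initial, "chain_state"), inherits(params, "chain_parameters"),
            inherits(config, "integrator_config"))
  grid_field <- inherits(field, "potential_grid")
  mode <- if (grid_field) "translocation" else if (!is.null(field)) "uniform" else "free"
  if (grid_field && is.null(geometry)) geometry <- field$geometry
  if (mode == "translocation" && !field$solved)
    stop("run_simulation: the potential grid must be solved first")
  wall_mode <- if (mode == "translocation") 1L else 0L
  geom_vec <- if (!is.null(geometry)) .geom_vec(geometry) else numeric(7)
  field_mode <- switch(mode, free = 0L, uniform = 1L, translocation = 2L)
  Euni <- if (mode == "uniform") {
    stopifnot(is.list(field), length(field$E) == 3)
    as.numeric(field$E)
  } else numeric(3)
  if (mode == "translocation") {
    gx <- field$gradient$x; gy <- field$gradient$y; gz <- field$gradient$z
    gmask <- as.integer(field$mask); gdims <- as.integer(field$dims)
    gorigin <- field$origin; gspacing <- field$spacing
  } else {
    gx <- gy <- gz <- 0; gmask <- 0L; gdims <- c(1L, 1L, 1L)
    gorigin <- numeric(3); gspacing <- 1
  }
  ## per-step displacement safety cap: half a bead diameter
  max_disp_nm <- 0.5 * params$sigma
  res <- with_seed(config$seed,
    ld_run_cpp(initial$positions, params$k_spring, params$r_eq, params$sigma,
               params$omega, params$cutoff, params$zeta, params$Q,
               config$temperature, config$dt, config$n_steps,
               config$output_stride, config$snapshot_stride, wall_mode, geom_vec,
               field_mode, Euni, gx, gy, gz, gmask, gdims, gorigin, gspacing,
               tether_k, initial$positions, max_disp_nm, config$seed))
  structure(list(times = initial$time + res$times, com = res$com,
                 snapshots = if (config$snapshot_stride > 0) res$snapshots else NULL,
                 final = chain_state(res$final,
                                     initial$time + config$n_steps * config$dt),
                 mode = mode,
                 field = if (mode == "uniform") list(E = Euni)
                         else if (mode == "translocation") "potential_grid"
                         else NULL,
                 geometry = geometry, seed = config$seed, dt = config$dt,
                 output_stride = config$output_stride,
                 snapshot_stride = config$snapshot_stride,
                 n_capped = res$n_capped, n_reflected = res$n_reflected,
                 n_rejected = res$n_rejected,
                 package_version = as.character(packageVersion("poredyn"))),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s mode): %d frames over %.4g s, seed %d\n",
              x$mode, length(x$times), x$times[length(x$times)] - x$times[1], x$seed))
  if (!is.null(x$snapshots)) cat(sprintf("  %d bead snapshots\n", length(x$snapshots)))
  if (x$n_reflected + x$n_rejected > 0)
    cat(sprintf("  wall events: %g reflected, %g rejected moves\n",
                x$n_reflected, x$n_rejected))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::plot(x$times, x$com[, 1], type = "l", xlab = "time (s)",
                 ylab = "centre of mass x (nm)", ...)
  invisible(x)
}

#' Place a coiled chain before the channel entrance
#'
#' Generates an equilibrium initial configuration and translates it so the
#' centre of mass sits one ensemble radius of gyration (sqrt(l_p * L_c))
#' before the channel entrance, centred in y and z — the standard starting
#' condition of the translocation runs.
#'
#' @param params a [chain_parameters()] object.
#' @param geometry a [channel_geometry()].
#' @param seed RNG seed.
#' @return a [chain_state()].
#' @export
place_at_entrance <- function(params, geometry, seed) {
  rg <- sqrt(params$sigma * params$N * params$r_eq)
  initialize_chain(params, start = c(-rg, 0, 0), seed = seed)
}
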