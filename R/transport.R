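#' Diffusion coefficient from free-solution trajectories
#'
#' Einstein-relation estimator: the mean square displacement of the chain
#' centre of mass is computed per trajectory with time-origin averaging,
#' averaged over the ensemble, and fitted by least squares over the recorded
#' window (excluding the first 5 percent of lags as transient); the slope
#' divided by 6 is D. The standard error comes from the spread of
#' per-trajectory slopes, which is robust to the strong correlation of MSD
#' points within a trajectory.
#'
#' @param trajectories list of free-solution [run_simulation()] trajectories
#'   recorded on a common time grid (>= 2 trajectories).
#' @param max_lag_frac largest lag used, as a fraction of the trajectory
#'   length (default 0.1; short lags carry most of the information).
#' @param time_average average over time origins within each trajectory
#'   (default TRUE).
#' @return object of class `transport_estimate` with fields `D` (m^2/s),
#'   `stderr`, `slope`, `intercept`, `n` and the fitted MSD curve.
#' @export
estimate_diffusion <- function(trajectories, max_lag_frac = 0.1, time_average = TRUE) {
  .check_traj_set(trajectories)
  msd <- lapply(trajectories, .traj_msd, max_lag_frac = max_lag_frac,
                time_average = time_average)
  lags <- msd[[1]]$lag
  curves <- vapply(msd, function(m) m$msd, numeric(length(lags)))
  keep <- lags > 0.05 * max(lags)
  slopes <- apply(curves, 2, function(y) coef(lm(y[keep] ~ lags[keep]))[2])
  fit <- lm(rowMeans(curves)[keep] ~ lags[keep])
  slope <- mean(slopes)
  se <- sd(slopes) / sqrt(length(slopes))
  structure(list(D = slope / 6, stderr = se / 6, slope = slope,
                 intercept = unname(coef(fit)[1]), n = length(trajectories),
                 lag = lags, msd = rowMeans(curves), quantity = "D",
                 units = "m^2/s"),
            class = "transport_estimate")
}

#' Electrophoretic mobility from uniform-field trajectories
#'
#' Least-squares slope of the ensemble-mean centre-of-mass displacement along
#' the drift direction versus time, divided by the applied field strength.
#'
#' @param trajectories list of uniform-field trajectories on a common time
#'   grid (>= 2).
#' @param E applied field strength magnitude (V/m), > 0.
#' @return object of class `transport_estimate` with `mu` (m^2/Vs), `stderr`
#'   and the per-trajectory drift velocities.
#' @export
estimate_mobility <- function(trajectories, E) {
  .check_traj_set(trajectories)
  stopifnot(is.numeric(E), E > 0)
  times <- trajectories[[1]]$times
  disp <- vapply(trajectories, function(tr) {
    d <- sweep(tr$com, 2, tr$com[1, ]) * 1e-9
    ## project on the mean drift direction of the ensemble member
    d
  }, matrix(0, length(times), 3))
  mean_disp <- apply(disp, c(1, 2), mean)
  drift_dir <- mean_disp[nrow(mean_disp), ]
  nrm <- sqrt(sum(drift_dir^2))
  if (nrm < 1e-300) stop("estimate_mobility: no net drift in the ensemble")
  drift_dir <- drift_dir / nrm
  proj <- apply(disp, 3, function(d) d %*% drift_dir)
  vel <- apply(proj, 2, function(p) coef(lm(p ~ times))[2])
  v <- mean(vel)
  se <- sd(vel) / sqrt(length(vel))
  structure(list(mu = abs(v) / E, stderr = se / E, velocity = v,
                 velocities = vel, E = E, n = length(trajectories),
                 quantity = "mu", units = "m^2/Vs"),
            class = "transport_estimate")
}

#' @export
print.transport_estimate <- function(x, ...) {
  if (x$quantity == "D")
    cat(sprintf("D = %.4g +/- %.2g m^2/s (ensemble of %d runs)\n", x$D, x$stderr, x$n))
  else
    cat(sprintf("mu = %.4g +/- %.2g m^2/Vs at E = %.3g V/m (%d runs)\n",
                x$mu, x$stderr, x$E, x$n))
  invisible(x)
}

.check_traj_set <- function(trajectories) {
  if (!is.list(trajectories) || length(trajectories) < 2)
    stop("at least 2 trajectories are required")
  nf <- vapply(trajectories, function(tr) length(tr$times), 1L)
  if (any(nf < 2)) stop("insufficient data: trajectories need at least 2 frames")
  if (length(unique(nf)) != 1) stop("trajectories must share a common time grid")
}

## time-origin-averaged MSD of the com track (m^2) at integer-frame lags
.traj_msd <- function(tr, max_lag_frac, time_average) {
  com <- tr$com * 1e-9
  nf <- nrow(com)
  dtf <- tr$times[2] - tr$times[1]
  max_lag <- max(1L, floor((nf - 1) * max_lag_frac))
  lags <- unique(round(seq(1, max_lag, length.out = min(max_lag, 100L))))
  msd <- vapply(lags, function(L) {
    d <- com[seq(1 + L, nf), , drop = FALSE] - com[seq(1, nf - L), , drop = FALSE]
    if (!time_average) d <- d[1, , drop = FALSE]
    mean(rowSums(d^2))
  }, 0)
  list(lag = lags * dtf, msd = msd)
}

#' Bead occupancy of the nanopore
#'
#' Counts, per recorded snapshot, the beads whose x-coordinate lies in the
#' half-open pore interval. The clock is re-zeroed at the first frame with
#' non-zero occupancy and the series ends when the occupancy returns to zero
#' after the last bead leaves. A chain that never enters yields an empty
#' series with `entered = FALSE` (not an error).
#'
#' @param trajectory a [run_simulation()] trajectory with snapshots.
#' @param geometry a [channel_geometry()].
#' @return object of class `occupancy_series`: `times` (s, re-zeroed),
#'   `n_pore` (bead counts), `pore_interval` (nm) and `entered`.
#' @export
pore_occupancy <- function(trajectory, geometry) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(geometry, "channel_geometry"))
  if (is.null(trajectory$snapshots))
    stop("pore_occupancy: the trajectory has no bead snapshots")
  px0 <- geometry$pore_start_x
  px1 <- px0 + geometry$pore_length
  counts <- vapply(trajectory$snapshots,
                   function(s) sum(s[, 1] >= px0 & s[, 1] < px1), 0L)
  tsn <- trajectory$times[1] +
    (seq_along(counts) - 1) * trajectory$snapshot_stride * trajectory$dt
  first <- which(counts > 0L)[1]
  if (is.na(first)) {
    return(structure(list(times = numeric(0), n_pore = integer(0),
                          pore_interval = c(px0, px1), entered = FALSE),
                     class = "occupancy_series"))
  }
  last <- max(which(counts > 0L))
  idx <- first:min(last + 1L, length(counts))
  structure(list(times = tsn[idx] - tsn[first], n_pore = counts[idx],
                 pore_interval = c(px0, px1), entered = TRUE),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  if (!x$entered) cat("Occupancy series: chain never entered the pore\n")
  else cat(sprintf("Occupancy series: %d frames, max %d beads in pore [%g, %g) nm\n",
                   length(x$n_pore), max(x$n_pore), x$pore_interval[1],
                   x$pore_interval[2]))
  invisible(x)
}

#' @export
plot.occupancy_series <- function(x, ...) {
  graphics::plot(x$times, x$n_pore, type = "s", xlab = "time since entry (s)",
                 ylab = "beads in pore", ...)
  invisible(x)
}

#' Folding-state histogram of pore occupancy
#'
#' Pools the occupancy counts of one or more series into an integer-binned
#' histogram and classifies each frame by its folding state: with b the
#' unfolded single-strand baseline, a count near (m+1) b is labelled m-fold
#' (an m-fold configuration threads m+1 strands through the pore
#' simultaneously). The baseline is taken as the mode of the counts below 1.5
#' times the geometric single-strand estimate (pore_length / r_eq + 1).
#'
#' @param series a single `occupancy_series` or a list of them.
#' @param params a [chain_parameters()] object (for r_eq).
#' @param pore_length pore length (nm); defaults to the interval stored in the
#'   first series.
#' @return list with the integer `histogram`, the `baseline` b, per-frame
#'   `labels` ("unfolded", "1-fold", ...), the `peaks` (count value and weight
#'   of each local histogram maximum) and the normalized `distribution` of
#'   fold states.
#' @export
fold_state_histogram <- function(series, params, pore_length = NULL) {
  if (inherits(series, "occupancy_series")) series <- list(series)
  stopifnot(inherits(params, "chain_parameters"))
  series <- Filter(function(s) isTRUE(s$entered) && length(s$n_pore) > 0, series)
  if (!length(series)) stop("fold_state_histogram: all series are empty")
  if (is.null(pore_length))
    pore_length <- diff(series[[1]]$pore_interval)
  counts <- unlist(lapply(series, function(s) s$n_pore))
  counts <- counts[counts > 0]
  geo_est <- pore_length / params$r_eq + 1
  low <- counts[counts <= 1.5 * geo_est]
  if (!length(low)) low <- counts
  tab <- table(low)
  baseline <- as.numeric(names(tab)[which.max(tab)])
  m <- pmax(0L, as.integer(round(counts / baseline)) - 1L)
  labels <- ifelse(m == 0L, "unfolded", paste0(m, "-fold"))
  hist_tab <- table(factor(counts, levels = seq_len(max(counts))))
  h <- as.numeric(hist_tab)
  is_peak <- vapply(seq_along(h), function(i) {
    h[i] > 0 &&
      h[i] >= (if (i > 1) h[i - 1] else 0) &&
      h[i] >= (if (i < length(h)) h[i + 1] else 0)
  }, TRUE)
  dist_tab <- tapply(rep(1, length(m)), factor(m, levels = 0:max(m)), sum)
  dist_tab[is.na(dist_tab)] <- 0
  distribution <- dist_tab / sum(dist_tab)
  list(histogram = hist_tab, baseline = baseline, labels = labels,
       peaks = data.frame(n_pore = which(is_peak), weight = h[is_peak] / sum(h)),
       distribution = distribution)
}

#' Centre-of-mass velocity profile
#'
#' Central-difference velocities of the recorded centre-of-mass track,
#' averaged within bins of the centre-of-mass position x_G measured from the
#' channel entrance. Empty bins are reported as NA (gaps), never interpolated.
#'
#' @param trajectories list of translocation trajectories.
#' @param bin_width bin width along x_G (nm), > 0.
#' @param xlim optional range of x_G to cover (nm); defaults to the data range.
#' @return data.frame with bin centre `x_G` (nm), mean velocity `v_G` (m/s),
#'   its standard error and the per-bin sample count.
#' @export
com_velocity_profile <- function(trajectories, bin_width, xlim = NULL) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  stopifnot(bin_width > 0)
  xs <- numeric(0); vs <- numeric(0)
  for (tr in trajectories) {
    x <- tr$com[, 1]
    t <- tr$times
    n <- length(x)
    if (n < 3) next
    v <- (x[-(1:2)] - x[seq_len(n - 2)]) * 1e-9 / (t[-(1:2)] - t[seq_len(n - 2)])
    xs <- c(xs, x[2:(n - 1)])
    vs <- c(vs, v)
  }
  if (!length(xs)) stop("com_velocity_profile: no usable frames")
  if (is.null(xlim)) xlim <- range(xs)
  breaks <- seq(floor(xlim[1] / bin_width) * bin_width,
                ceiling(xlim[2] / bin_width) * bin_width, by = bin_width)
  bin <- cut(xs, breaks, include.lowest = TRUE)
  agg <- function(f) as.numeric(tapply(vs, bin, f))
  cnt <- as.numeric(tapply(vs, bin, length))
  cnt[is.na(cnt)] <- 0
  data.frame(x_G = (breaks[-1] + breaks[-length(breaks)]) / 2,
             v_G = agg(mean),
             stderr = agg(function(v) sd(v) / sqrt(length(v))),
             n = cnt)
}

#' Reduced-theory inputs
#'
#' Container for the tabulated quantities entering the analytic transport
#' theory: the (magnitude of the) axial field in the channel and in the pore,
#' the mean bead occupancy of the pore, the bead-uptake gradient dN/dx of the
#' entry stage, and the entry velocity.
#'
#' @param E_channel,E_pore field magnitudes (V/m).
#' @param N_pore_mean mean number of beads in the pore.
#' @param dN_dx beads taken up per metre of centre-of-mass advance (1/m).
#' @param v0 entry velocity (m/s).
#' @return object of class `theory_inputs`.
#' @export
theory_inputs <- function(E_channel = 0, E_pore = 0, N_pore_mean = 0, dN_dx = 0,
                          v0 = 0) {
  stopifnot(E_channel >= 0, E_pore >= 0, N_pore_mean >= 0, dN_dx >= 0)
  structure(list(E_channel = E_channel, E_pore = E_pore,
                 N_pore_mean = N_pore_mean, dN_dx = dN_dx, v0 = v0),
            class = "theory_inputs")
}

#' Theoretical entry-stage velocity slope
#'
#' During entry the chain feeds beads into the almost uniform channel field at
#' a rate dN/dx, so the centre-of-mass velocity grows linearly with position:
#' dv_G/dx_G = |Q| E_channel (dN/dx) / (N zeta).
#'
#' @param params a [chain_parameters()] object.
#' @param inputs a [theory_inputs()] object.
#' @return slope (1/s).
#' @export
theory_entry_slope <- function(params, inputs) {
  stopifnot(inherits(params, "chain_parameters"), inherits(inputs, "theory_inputs"))
  abs(params$Q) * inputs$E_channel * inputs$dN_dx / (params$N * params$zeta)
}

#' Theoretical terminal centre-of-mass velocity
#'
#' Once the occupancy of the pore is steady and the stretched chain rarely
#' touches the walls (counteracting forces negligible), the terminal velocity
#' is the field-weighted partition of beads between pore and channel:
#' v_G = |Q| (N_pore E_pore + (N - N_pore) E_channel) / (N zeta).
#' In the uniform-field limit E_pore = E_channel = E this reduces exactly to
#' the free-solution drift mu E.
#'
#' @param params a [chain_parameters()] object.
#' @param inputs a [theory_inputs()] object; `N_pore_mean` must not exceed N.
#' @return terminal velocity (m/s).
#' @export
theory_terminal_velocity <- function(params, inputs) {
  stopifnot(inherits(params, "chain_parameters"), inherits(inputs, "theory_inputs"))
  if (inputs$N_pore_mean > params$N)
    stop("theory_terminal_velocity: N_pore_mean exceeds the chain length")
  abs(params$Q) * (inputs$N_pore_mean * inputs$E_pore +
                   (params$N - inputs$N_pore_mean) * inputs$E_channel) /
    (params$N * params$zeta)
}
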