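#' Reservoir / nanochannel / nanopore geometry
#'
#' Axis-aligned description of the fluidic domain: a rectangular nanochannel of
#' length `channel_length` spanning x in \[0, L\] (x = 0 is the cis entrance),
#' laterally centred on y = z = 0, with a nanopore slab of reduced cross-section
#' replacing the channel over \[pore_start_x, pore_start_x + pore_length\], and
#' a reservoir block on either side. Electrode (Dirichlet) planes close the
#' reservoirs at `electrode_offset` from the channel entrances.
#'
#' @param reservoir_dims 3-vector (length, width, height), nm, of each
#'   reservoir; `c(0, 0, 0)` places the electrodes directly on the channel end
#'   planes (plain duct, useful for validation).
#' @param channel_length,channel_width,channel_height channel box (nm).
#' @param pore_length,pore_width,pore_height pore box (nm); pore cross-section
#'   must fit inside the channel cross-section.
#' @param pore_start_x channel-local x of the pore entrance (nm).
#' @param electrode_potentials `c(cis, trans)` voltages (V).
#' @param electrode_offset distance of the electrode planes from the channel
#'   entrances (nm); defaults to the reservoir length.
#' @return an object of class `channel_geometry`.
#' @examples
#' geo <- preset_geometry("paper_30x30")
#' geo$pore_start_x + c(0, geo$pore_length)  # pore spans 1000..1200 nm
#' @export
channel_geometry <- function(reservoir_dims = c(2500, 4000, 500),
                             channel_length = 2200, channel_width = 500,
                             channel_height = 30, pore_length = 200,
                             pore_width = 30, pore_height = 30,
                             pore_start_x = 1000,
                             electrode_potentials = c(-0.4, 0.4),
                             electrode_offset = reservoir_dims[1]) {
  g <- list(reservoir_dims = as.numeric(reservoir_dims),
            channel_length = channel_length, channel_width = channel_width,
            channel_height = channel_height, pore_length = pore_length,
            pore_width = pore_width, pore_height = pore_height,
            pore_start_x = pore_start_x,
            electrode_potentials = as.numeric(electrode_potentials),
            electrode_offset = electrode_offset)
  num <- c(g[!names(g) %in% c("reservoir_dims", "electrode_potentials")],
           as.list(g$reservoir_dims), as.list(g$electrode_potentials))
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)))
    stop("channel_geometry: all dimensions and potentials must be finite scalars")
  if (any(c(g$channel_length, g$channel_width, g$channel_height, g$pore_length,
            g$pore_width, g$pore_height) <= 0) || any(g$reservoir_dims < 0))
    stop("channel_geometry: box dimensions must be positive")
  if (g$pore_width > g$channel_width || g$pore_height > g$channel_height)
    stop("channel_geometry: pore cross-section exceeds the channel cross-section")
  if (g$pore_start_x < 0 || g$pore_start_x + g$pore_length > g$channel_length)
    stop("channel_geometry: pore must lie fully inside the channel along x")
  if (length(g$electrode_potentials) != 2)
    stop("channel_geometry: electrode_potentials must be length 2 (cis, trans)")
  structure(g, class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Channel %g x %g x %g nm, pore %g x %g x %g nm at x = [%g, %g] nm\n",
              x$channel_length, x$channel_width, x$channel_height, x$pore_length,
              x$pore_width, x$pore_height, x$pore_start_x,
              x$pore_start_x + x$pore_length))
  cat(sprintf("Reservoirs %g x %g x %g nm; electrodes %+.3g / %+.3g V at offset %g nm\n",
              x$reservoir_dims[1], x$reservoir_dims[2], x$reservoir_dims[3],
              x$electrode_potentials[1], x$electrode_potentials[2], x$electrode_offset))
  invisible(x)
}

## wall-plane vector handed to the compiled kernels:
## (ch_len, ch_halfwidth, ch_halfheight, pore_x0, pore_x1, pore_halfwidth, pore_halfheight)
.geom_vec <- function(geometry) {
  c(geometry$channel_length, geometry$channel_width / 2, geometry$channel_height / 2,
    geometry$pore_start_x, geometry$pore_start_x + geometry$pore_length,
    geometry$pore_width / 2, geometry$pore_height / 2)
}

#' Discretize the fluid domain onto a regular node lattice
#'
#' Builds the interior mask of a [potential_grid]: the union of the two
#' reservoirs, the channel, and the pore (which replaces the channel
#' cross-section over its x-extent). Nodes strictly inside the open fluid boxes
#' are interior; the insulating walls then lie half a cell beyond the outermost
#' interior nodes (consistent with the mirror-node Neumann treatment of the
#' solver). Electrode planes are marked as Dirichlet nodes.
#'
#' @param geometry a [channel_geometry()].
#' @param spacing lattice spacing (nm); must divide the box dimensions to
#'   within half a cell and resolve the pore half-width.
#' @return an object of class `potential_grid` with the mask initialized and
#'   potential values unset.
#' @export
build_geometry <- function(geometry, spacing = 10) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (spacing <= 0) stop("build_geometry: spacing must be positive")
  if (spacing > geometry$pore_width / 2 || spacing > geometry$pore_height / 2)
    stop("build_geometry: spacing coarser than the pore half-width cannot resolve the pore")
  dims_nm <- c(geometry$channel_length, geometry$channel_width, geometry$channel_height,
               geometry$pore_length, geometry$pore_width, geometry$pore_height,
               geometry$pore_start_x, geometry$reservoir_dims, geometry$electrode_offset)
  off <- abs(dims_nm / spacing - round(dims_nm / spacing))
  if (any(off > 0.05 + 1e-9))
    stop("build_geometry: spacing must divide the box dimensions (to within half a cell of rounding)")

  res_len <- geometry$electrode_offset
  has_res <- res_len > 0
  res_hw <- if (has_res) geometry$reservoir_dims[2] / 2 else geometry$channel_width / 2
  res_hh <- if (has_res) geometry$reservoir_dims[3] / 2 else geometry$channel_height / 2
  ch_len <- geometry$channel_length
  ch_hw <- geometry$channel_width / 2
  ch_hh <- geometry$channel_height / 2
  px0 <- geometry$pore_start_x
  px1 <- px0 + geometry$pore_length
  p_hw <- geometry$pore_width / 2
  p_hh <- geometry$pore_height / 2

  ## Finite-volume style lattice: each node owns a cell of edge `spacing`
  ## centred on it; a node is fluid when its cell lies inside the region's
  ## open box, so box faces coincide with cell faces wherever the dimensions
  ## allow. Along x the lattice is cell-centred (faces at multiples of the
  ## spacing, which the box edges are). Laterally the node offset is chosen
  ## so that the pore walls - the smallest, most field-sensitive faces -
  ## land exactly on cell faces; wider walls may be represented up to half a
  ## cell inward.
  s <- spacing
  eps <- 1e-6
  xg <- seq(-res_len + s / 2, ch_len + res_len - s / 2, by = s)
  lat_nodes <- function(p_half, half_max) {
    off <- (p_half - s / 2) %% s
    kmax <- floor((half_max - s / 2 - off) / s + eps)
    if (off < eps) c(rev(seq(-off - s, by = -s, length.out = kmax)),
                     seq(off, by = s, length.out = kmax + 1))
    else sort(c(seq(-off, by = -s, length.out = kmax + 1),
                seq(off, by = s, length.out = kmax + 1)))
  }
  yg <- lat_nodes(p_hw, max(res_hw, ch_hw))
  zg <- lat_nodes(p_hh, max(res_hh, ch_hh))
  nx <- length(xg); ny <- length(yg); nz <- length(zg)

  inside <- function(v, half) abs(v) <= half - s / 2 + eps
  mask <- array(0L, dim = c(nx, ny, nz))
  ylat <- matrix(rep(yg, nz), ny, nz)
  zlat <- matrix(rep(zg, each = ny), ny, nz)
  res_cs <- inside(ylat, res_hw) & inside(zlat, res_hh)
  ch_cs <- inside(ylat, ch_hw) & inside(zlat, ch_hh)
  p_cs <- inside(ylat, p_hw) & inside(zlat, p_hh)
  for (i in seq_len(nx)) {
    x <- xg[i]
    cs <- if (x < 0 || x > ch_len) res_cs
          else if (x > px0 && x < px1) p_cs
          else ch_cs
    mask[i, , ][cs] <- 1L
  }
  if (has_res) {
    mask[1, , ][res_cs] <- 2L
    mask[nx, , ][res_cs] <- 2L
  } else {
    mask[1, , ][ch_cs] <- 2L
    mask[nx, , ][mask[nx, , ] == 1L] <- 2L
  }
  if (any(apply(mask > 0, 1, sum) == 0))
    stop("build_geometry: mask is disconnected along x (empty cross-section plane)")

  structure(list(origin = c(xg[1], yg[1], zg[1]), spacing = spacing,
                 dims = c(nx, ny, nz), x = xg, y = yg, z = zg, mask = mask,
                 values = NULL, gradient = NULL, solved = FALSE,
                 geometry = geometry),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("Potential grid %d x %d x %d nodes, spacing %g nm, %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              if (x$solved) "solved" else "values unset"))
  invisible(x)
}

#' Solve the Laplace equation on the masked lattice
#'
#' Red-black successive over-relaxation for `grad^2 phi = 0` with insulating
#' (zero normal gradient) walls, implemented by ghost-node mirroring, and fixed
#' potentials on the electrode planes. The converged solution satisfies
#' discrete flux conservation across every channel cross-section (see
#' [cross_section_current()]).
#'
#' @param grid a [build_geometry()] result.
#' @param tolerance convergence threshold on the maximum nodal residual (V).
#' @param max_iter iteration budget; exceeding it raises an error reporting the
#'   final residual.
#' @param omega over-relaxation factor; default near-optimal for the lattice.
#' @return the grid with `values` (V) populated, the nodal potential gradient
#'   cached, and `solved = TRUE`.
#' @export
solve_laplace <- function(grid, tolerance = 1e-9, max_iter = 50000, omega = NULL) {
  stopifnot(inherits(grid, "potential_grid"))
  pots <- grid$geometry$electrode_potentials
  nx <- grid$dims[1]
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(grid$dims)))
  ## initial guess: linear ramp in x between the electrode potentials
  ramp <- pots[1] + (pots[2] - pots[1]) * (seq_len(nx) - 1) / (nx - 1)
  phi <- array(rep(ramp, times = prod(grid$dims[2:3])), dim = grid$dims)
  phi[grid$mask == 0L] <- 0
  phi[1, , ][grid$mask[1, , ] == 2L] <- pots[1]
  phi[nx, , ][grid$mask[nx, , ] == 2L] <- pots[2]
  res <- sor_solve_cpp(phi, as.integer(grid$mask), as.integer(grid$dims),
                       omega, tolerance, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("solve_laplace: no convergence in %d iterations (residual %.3g V)",
                 res$iterations, res$residual))
  grid$values <- phi
  grid$gradient <- .grid_gradient(phi, grid$mask, grid$spacing)
  grid$solved <- TRUE
  grid$iterations <- res$iterations
  grid$residual <- res$residual
  grid
}

## nodal gradient of phi (V/m) by central differences, one-sided at walls,
## zero where no fluid neighbour exists along the axis
.grid_gradient <- function(phi, mask, spacing_nm) {
  d <- dim(phi)
  h <- spacing_nm * 1e-9
  fluid <- mask > 0L
  grad <- list()
  for (ax in 1:3) {
    n <- d[ax]
    idx <- function(k) {
      i <- pmin(pmax(seq_len(d[1]) + if (ax == 1) k else 0, 1), d[1])
      j <- pmin(pmax(seq_len(d[2]) + if (ax == 2) k else 0, 1), d[2])
      l <- pmin(pmax(seq_len(d[3]) + if (ax == 3) k else 0, 1), d[3])
      list(i = i, j = j, l = l)
    }
    sh <- function(A, k) {
      ii <- idx(k)
      A[ii$i, ii$j, ii$l, drop = FALSE]
    }
    at_edge_lo <- function() { # TRUE where the -1 neighbour is off-lattice
      e <- array(FALSE, d)
      if (ax == 1) e[1, , ] <- TRUE else if (ax == 2) e[, 1, ] <- TRUE else e[, , 1] <- TRUE
      e
    }
    at_edge_hi <- function() {
      e <- array(FALSE, d)
      if (ax == 1) e[n, , ] <- TRUE else if (ax == 2) e[, n, ] <- TRUE else e[, , n] <- TRUE
      e
    }
    pm <- sh(phi, -1L); pp <- sh(phi, +1L)
    fm <- sh(fluid, -1L) & !at_edge_lo()
    fp <- sh(fluid, +1L) & !at_edge_hi()
    g <- array(0, d)
    both <- fm & fp
    g[both] <- (pp[both] - pm[both]) / (2 * h)
    lo <- fm & !fp
    g[lo] <- (phi[lo] - pm[lo]) / h
    hi <- fp & !fm
    g[hi] <- (pp[hi] - phi[hi]) / h
    g[!fluid] <- 0
    grad[[ax]] <- g
  }
  names(grad) <- c("x", "y", "z")
  grad
}

#' Electrostatic potential along the channel axis
#'
#' Samples phi along the centreline y = z = 0 from the cis electrode to the
#' trans electrode. The potential is monotone between the electrodes and, for
#' a pore narrower than the channel, its steepest drop falls inside the pore
#' interval.
#'
#' @param grid a solved [potential_grid].
#' @return data.frame with columns `x` (nm) and `phi` (V).
#' @export
potential_profile_on_axis <- function(grid) {
  stopifnot(inherits(grid, "potential_grid"))
  if (!grid$solved) stop("potential_profile_on_axis: grid is not solved yet")
  j <- which.min(abs(grid$y))
  k <- which.min(abs(grid$z))
  keep <- grid$mask[, j, k] > 0L
  data.frame(x = grid$x[keep], phi = grid$values[, j, k][keep])
}

#' Electric force on a point charge in the solved field
#'
#' Mask-weighted trilinear interpolation of the nodal potential gradient at the
#' given positions; the force is `-Q * grad(phi)`. For a linear potential the
#' constant field is reproduced exactly. Positions farther than one cell from
#' the fluid domain raise an error.
#'
#' @param position 3-vector or n x 3 matrix of positions (nm).
#' @param grid a solved [potential_grid].
#' @param Q charge (C).
#' @return force vector(s) (N), same shape as `position`.
#' @export
electric_force_at <- function(position, grid, Q) {
  stopifnot(inherits(grid, "potential_grid"))
  if (!grid$solved) stop("electric_force_at: grid is not solved yet")
  vec_in <- is.null(dim(position))
  pos <- if (vec_in) matrix(position, 1, 3) else as.matrix(position)
  ## domain check: nearest node (or any node within one cell) must be fluid
  for (r in seq_len(nrow(pos))) {
    ii <- round((pos[r, ] - grid$origin) / grid$spacing) + 1
    lo <- pmax(ii - 1, 1)
    hi <- pmin(ii + 1, grid$dims)
    if (any(ii < 0) || any(ii > grid$dims + 1) ||
        !any(grid$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] > 0L))
      stop("electric_force_at: position outside the fluid domain by more than one cell")
  }
  g <- grad_interp_cpp(pos, grid$gradient$x, grid$gradient$y, grid$gradient$z,
                       as.integer(grid$mask), as.integer(grid$dims),
                       grid$origin, grid$spacing)
  out <- -Q * g
  if (vec_in) drop(out) else out
}

#' Discrete current through cross-section planes
#'
#' Sums the x-component of `grad phi` over the lattice faces between
#' consecutive x-planes (a Kirchhoff current analogue, up to conductivity).
#' For a converged solution this is constant along x to within the solver
#' tolerance.
#'
#' @param grid a solved [potential_grid].
#' @return data.frame with the face-plane position `x` (nm) and the summed
#'   `current` (arbitrary units, proportional to A/m^2 times face area).
#' @export
cross_section_current <- function(grid) {
  stopifnot(inherits(grid, "potential_grid"), grid$solved)
  nx <- grid$dims[1]
  cur <- numeric(nx - 1)
  for (i in seq_len(nx - 1)) {
    f1 <- grid$mask[i, , ] > 0L
    f2 <- grid$mask[i + 1, , ] > 0L
    both <- f1 & f2
    cur[i] <- sum((grid$values[i + 1, , ][both] - grid$values[i, , ][both]))
  }
  data.frame(x = (grid$x[-nx] + grid$x[-1]) / 2, current = cur * grid$spacing * 1e-9)
}

#' Field strength at the centre of the pore and of the channel
#'
#' Convenience accessor mirroring the tabulated observables: the magnitude of
#' the axial potential gradient sampled at the pore centre and at the channel
#' centre (midpoint of the cis channel segment).
#'
#' @param grid a solved [potential_grid].
#' @return list with `E_pore` and `E_channel` (V/m).
#' @export
field_summary <- function(grid) {
  stopifnot(inherits(grid, "potential_grid"), grid$solved)
  geo <- grid$geometry
  pore_mid <- c(geo$pore_start_x + geo$pore_length / 2, 0, 0)
  chan_mid <- c(geo$pore_start_x / 2, 0, 0)
  gp <- grad_interp_cpp(rbind(pore_mid, chan_mid), grid$gradient$x, grid$gradient$y,
                        grid$gradient$z, as.integer(grid$mask), as.integer(grid$dims),
                        grid$origin, grid$spacing)
  list(E_pore = abs(gp[1, 1]), E_channel = abs(gp[2, 1]))
}
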