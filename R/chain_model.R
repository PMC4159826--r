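#' Coarse-grained chain parameters
#'
#' Low-level constructor for the full parameter set of the bead-spring ssDNA
#' model. Most users should call [derive_parameters()], which fills in every
#' derived field from the handful of physical inputs. All lengths are in nm,
#' energies in J, friction in kg/s, charge in C.
#'
#' The derived fields obey, by construction:
#' \itemize{
#'   \item \code{r_eq = alpha * r_nt * N_nt / N} (equilibrium bond length),
#'   \item \code{chi = 0.1 * sigma} and \code{k_spring = kB*T / chi^2},
#'   \item \code{zeta = kB*T / (N * D_target)} (per-bead friction),
#'   \item \code{Q = -mu_target * kB*T / (N * D_target)} (per-bead effective
#'         charge, negative for DNA),
#'   \item \code{cutoff = 2^(1/6) * sigma} (WCA truncation, purely repulsive).
#' }
#'
#' @param N number of beads (>= 1; bonds connect consecutive beads).
#' @param N_nt number of nucleotides represented.
#' @param r_nt internucleotide distance (nm).
#' @param alpha dimensionless contour-scale factor.
#' @param r_eq equilibrium bond length (nm).
#' @param chi bond-fluctuation length (nm).
#' @param k_spring harmonic spring constant (N/m).
#' @param sigma excluded-volume (WCA) length (nm).
#' @param omega WCA well depth (J).
#' @param cutoff pair-interaction truncation distance (nm); must exceed sigma.
#' @param zeta per-bead friction coefficient (kg/s).
#' @param Q per-bead signed charge (C); negative for DNA.
#' @param D_target reference chain diffusion coefficient (m^2/s).
#' @param mu_target reference electrophoretic mobility (m^2/Vs).
#' @param T temperature (K).
#' @return an object of class `chain_parameters`.
#' @seealso [derive_parameters()]
#' @export
chain_parameters <- function(N, N_nt, r_nt, alpha, r_eq, chi, k_spring, sigma,
                             omega, cutoff, zeta, Q, D_target, mu_target, T) {
  p <- list(N = N, N_nt = N_nt, r_nt = r_nt, alpha = alpha, r_eq = r_eq,
            chi = chi, k_spring = k_spring, sigma = sigma, omega = omega,
            cutoff = cutoff, zeta = zeta, Q = Q, D_target = D_target,
            mu_target = mu_target, T = T)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      stop("chain_parameters: field '", f, "' must be a finite scalar")
  }
  if (p$N < 1 || p$N != round(p$N)) stop("chain_parameters: N must be a positive integer")
  positive <- c("N_nt", "r_nt", "alpha", "r_eq", "chi", "k_spring", "sigma",
                "omega", "cutoff", "zeta", "D_target", "mu_target", "T")
  for (f in positive) if (p[[f]] <= 0)
    stop("chain_parameters: field '", f, "' must be positive")
  if (p$cutoff <= p$sigma) stop("chain_parameters: cutoff must exceed sigma")
  if (p$Q > 0) stop("chain_parameters: Q must carry the (negative) DNA sign")
  structure(p, class = "chain_parameters")
}

#' Derive all chain parameters from the physical inputs
#'
#' Pure arithmetic mapping from the model's physical inputs to the complete
#' bead-spring parameter set: the equilibrium bond length partitions the ssDNA
#' contour over the beads, the spring constant comes from the thermal
#' bond-fluctuation length chi = 0.1 sigma, and the per-bead friction and
#' effective charge are matched to the measured chain diffusion coefficient and
#' electrophoretic mobility through the Einstein relation N zeta D = kB T and
#' Q = zeta mu.
#'
#' With the defaults (a 48 knt chain mapped onto 400 beads, D = 2.21e-12 m2/s,
#' mu = 2.84e-8 m2/Vs, T = 300 K) this yields r_eq = 43.7 nm,
#' zeta = 4.69e-12 kg/s and Q = -0.83 e per bead.
#'
#' @param N number of beads (>= 2).
#' @param N_nt number of nucleotides (default 48000).
#' @param r_nt internucleotide distance, nm (default 0.43).
#' @param alpha contour-scale factor (default 0.847).
#' @param sigma WCA length, nm (default 5, the ssDNA persistence length).
#' @param omega_kT WCA well depth in units of kB*T (default 1).
#' @param D_target chain diffusion coefficient, m^2/s (default 2.21e-12).
#' @param mu_target electrophoretic mobility magnitude, m^2/Vs (default 2.84e-8).
#' @param T temperature, K (default 300).
#' @return a [chain_parameters()] object.
#' @examples
#' p <- derive_parameters(N = 400)
#' p$r_eq                     # 43.7 nm
#' p$Q / 1.602176634e-19      # -0.83 elementary charges
#' @export
derive_parameters <- function(N = 400, N_nt = 48000, r_nt = 0.43, alpha = 0.847,
                              sigma = 5, omega_kT = 1, D_target = 2.21e-12,
                              mu_target = 2.84e-8, T = 300) {
  vals <- list(N = N, N_nt = N_nt, r_nt = r_nt, alpha = alpha, sigma = sigma,
               omega_kT = omega_kT, D_target = D_target, mu_target = mu_target, T = T)
  for (f in names(vals)) {
    v <- vals[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("derive_parameters: input '", f, "' must be a positive finite scalar")
  }
  if (N < 2 || N != round(N)) stop("derive_parameters: N must be an integer >= 2")
  kBT <- .kB * T
  chi <- 0.1 * sigma
  chain_parameters(
    N = N, N_nt = N_nt, r_nt = r_nt, alpha = alpha,
    r_eq = alpha * r_nt * N_nt / N,
    chi = chi,
    k_spring = kBT / (chi * 1e-9)^2,
    sigma = sigma,
    omega = omega_kT * kBT,
    cutoff = 2^(1 / 6) * sigma,
    zeta = kBT / (N * D_target),
    Q = -mu_target * kBT / (N * D_target),
    D_target = D_target, mu_target = mu_target, T = T)
}

#' @export
print.chain_parameters <- function(x, ...) {
  cat("Coarse-grained bead-spring chain parameters\n")
  cat(sprintf("  beads N = %d (%g nt, %g nt/bead)\n", x$N, x$N_nt, x$N_nt / x$N))
  cat(sprintf("  bond: r_eq = %.4g nm, k = %.4g N/m (chi = %.3g nm)\n",
              x$r_eq, x$k_spring, x$chi))
  cat(sprintf("  WCA: sigma = %.3g nm, omega = %.4g J, cutoff = %.4g nm\n",
              x$sigma, x$omega, x$cutoff))
  cat(sprintf("  per bead: zeta = %.4g kg/s, Q = %.4g C (%.3g e)\n",
              x$zeta, x$Q, x$Q / .e_charge))
  cat(sprintf("  targets: D = %.4g m2/s, mu = %.4g m2/Vs, T = %g K\n",
              x$D_target, x$mu_target, x$T))
  invisible(x)
}

#' Chain configuration
#'
#' A chain state is the ordered set of bead positions (rows of an N x 3 matrix,
#' nm) plus the elapsed simulated time (s). Bond i connects beads i and i+1.
#'
#' @param positions N x 3 numeric matrix of bead coordinates (nm).
#' @param time elapsed simulated time (s).
#' @return an object of class `chain_state`.
#' @export
chain_state <- function(positions, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("chain_state: positions must be an N x 3 matrix")
  if (nrow(positions) < 1) stop("chain_state: at least one bead required")
  if (!all(is.finite(positions))) stop("chain_state: all coordinates must be finite")
  if (!is.numeric(time) || length(time) != 1 || !is.finite(time) || time < 0)
    stop("chain_state: time must be a finite non-negative scalar")
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions, time = time), class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("Chain state: %d beads, t = %.4g s, Rg = %.4g nm\n",
              nrow(x$positions), x$time, radius_of_gyration(x)))
  invisible(x)
}

#' Harmonic bond forces
#'
#' Force on each bead from the harmonic springs U = (k/2)(r_ij - r_eq)^2
#' connecting consecutive beads. Forces are the negative gradient of the total
#' bond energy and sum to zero over the chain.
#'
#' @param state a [chain_state()].
#' @param params a [chain_parameters()] object.
#' @return N x 3 matrix of forces (N).
#' @export
bond_forces <- function(state, params) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "chain_parameters"))
  bond_forces_cpp(state$positions, params$k_spring, params$r_eq)
}

#' Excluded-volume (WCA) forces
#'
#' Purely repulsive Weeks-Chandler-Andersen interaction between all
#' non-adjacent bead pairs: the Lennard-Jones potential shifted up by omega and
#' truncated at the cutoff (2^(1/6) sigma), so force and energy vanish at and
#' beyond the cutoff. Directly bonded neighbours do not interact through this
#' term.
#'
#' @param state a [chain_state()].
#' @param params a [chain_parameters()] object.
#' @param method `"cell"` (spatial-hash cell list, the default) or
#'   `"all_pairs"` (reference double loop). Both accumulate per-bead
#'   contributions in identical order and return bit-identical forces.
#' @return N x 3 matrix of forces (N).
#' @export
excluded_volume_forces <- function(state, params, method = c("cell", "all_pairs")) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "chain_parameters"))
  method <- match.arg(method)
  ev_forces_cpp(state$positions, params$sigma, params$omega, params$cutoff,
                if (method == "cell") 1L else 0L)
}

#' Intramolecular potential energy
#'
#' Total (or per-term) potential energy of a configuration: harmonic bonds plus
#' the WCA excluded-volume term. Used mainly to cross-check analytic forces
#' against numerical gradients.
#'
#' @param state a [chain_state()].
#' @param params a [chain_parameters()] object.
#' @param terms which contributions to include.
#' @return energy (J).
#' @export
potential_energy <- function(state, params, terms = c("bond", "ev")) {
  stopifnot(inherits(state, "chain_state"), inherits(params, "chain_parameters"))
  pos <- state$positions * 1e-9
  E <- 0
  n <- nrow(pos)
  if ("bond" %in% terms && n >= 2) {
    d <- sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-n, , drop = FALSE])^2))
    E <- E + sum(params$k_spring / 2 * (d - params$r_eq * 1e-9)^2)
  }
  if ("ev" %in% terms && n >= 3) {
    dm <- as.matrix(stats::dist(pos))
    sel <- upper.tri(dm) & abs(row(dm) - col(dm)) > 1
    r <- dm[sel]
    r <- r[r < params$cutoff * 1e-9]
    if (length(r)) {
      sr6 <- (params$sigma * 1e-9 / r)^6
      E <- E + sum(4 * params$omega * (sr6^2 - sr6) + params$omega)
    }
  }
  E
}

#' Radius of gyration
#'
#' Root-mean-square distance of the beads from their centroid (nm). Invariant
#' under rigid translation and rotation.
#'
#' @param state a [chain_state()] or an N x 3 position matrix (nm).
#' @return length (nm).
#' @export
radius_of_gyration <- function(state) {
  pos <- if (inherits(state, "chain_state")) state$positions else as.matrix(state)
  ctr <- colMeans(pos)
  sqrt(mean(rowSums(sweep(pos, 2, ctr)^2)))
}

## inverse of the Langevin-type function coth(k) - 1/k = c (mean cosine of a
## Fisher-distributed deflection); odd in c, so only |c| is solved for.
.fisher_kappa <- function(c) {
  if (abs(c) < 1e-12) return(0)
  f <- function(k) 1 / tanh(k) - 1 / k - abs(c)
  k <- uniroot(f, c(1e-8, 1e4), tol = 1e-12)$root
  sign(c) * k
}

#' Generate an initial chain configuration
#'
#' Builds a persistence-correlated random walk of fixed bond length r_eq: each
#' bond direction is drawn from a Fisher distribution about the previous one,
#' with the mean deflection cosine c chosen from the discrete worm-like-chain
#' (Kuhn) relation (1+c)/(1-c) = 6 l_p / r_eq so that the ensemble
#' root-mean-square radius of gyration matches sqrt(l_p * L_c), with
#' persistence length l_p = sigma and contour length L_c = N r_eq. Self-overlap
#' (non-adjacent beads closer than sigma) is rejected and resampled; generation
#' aborts after a bounded number of restarts.
#'
#' For the 48 knt / 400 bead chain this gives an ensemble rms Rg of about
#' 296 nm, i.e. a coil in the vicinity of 300 nm.
#'
#' @param params a [chain_parameters()] object.
#' @param start 3-vector (nm): target centre of mass of the generated chain.
#' @param seed RNG seed (required, for reproducibility).
#' @param persistence persistence length l_p (nm); default `params$sigma`.
#' @param max_restarts abort after this many whole-chain restarts.
#' @return a [chain_state()] with all bond lengths equal to r_eq.
#' @export
initialize_chain <- function(params, start = c(0, 0, 0), seed,
                             persistence = params$sigma, max_restarts = 100) {
  stopifnot(inherits(params, "chain_parameters"))
  if (missing(seed)) stop("initialize_chain: a seed is required")
  stopifnot(length(start) == 3, all(is.finite(start)))
  N <- params$N
  b <- params$r_eq
  ratio <- 6 * persistence / b
  cbar <- (ratio - 1) / (ratio + 1)
  kappa <- .fisher_kappa(cbar)
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      pos <- .grow_chain(N, b, kappa, params$sigma)
      if (!is.null(pos)) {
        pos <- sweep(pos, 2, colMeans(pos)) # centre, then translate to start
        pos <- sweep(pos, 2, start, "+")
        return(chain_state(pos, time = 0))
      }
    }
    stop("initialize_chain: failed to generate a non-overlapping chain after ",
         max_restarts, " restarts")
  })
}

## grow one chain; NULL on irrecoverable overlap
.grow_chain <- function(N, b, kappa, sigma) {
  pos <- matrix(0, N, 3)
  if (N == 1) return(pos)
  u <- .rand_unit()
  pos[2, ] <- pos[1, ] + b * u
  for (i in seq_len(N - 2) + 2L) {
    placed <- FALSE
    for (try in 1:50) {
      v <- .fisher_step(u, kappa)
      cand <- pos[i - 1, ] + b * v
      prev <- pos[seq_len(i - 2), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (all(d2 >= sigma^2)) {
        pos[i, ] <- cand
        u <- v
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  pos
}

.rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

## one Fisher-distributed unit step with mean direction u (kappa may be
## negative: concentration towards -u)
.fisher_step <- function(u, kappa) {
  if (abs(kappa) < 1e-10) return(.rand_unit())
  mu <- if (kappa > 0) u else -u
  k <- abs(kappa)
  uu <- runif(1)
  w <- 1 + log(uu + (1 - uu) * exp(-2 * k)) / k
  w <- max(min(w, 1), -1)
  # orthonormal frame around mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  phi <- runif(1, 0, 2 * pi)
  s <- sqrt(max(0, 1 - w^2))
  w * mu + s * (cos(phi) * e1 + sin(phi) * e2)
}
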