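# Shared fixtures: physical constants and small parameter sets used across tests.
kB <- 1.380649e-23
e_charge <- 1.602176634e-19

paper_params <- derive_parameters(N = 400)
scaled_params <- preset_chain("scaled")

# a small chain for force tests (10 beads, scaled bead size)
small_params <- derive_parameters(N = 10, N_nt = 120, r_nt = 0.43, alpha = 0.847,
                                  sigma = 5, D_target = 2.21e-12 * 40)

# random small chain with some pairs inside the WCA cutoff
crumpled_chain <- function(params, seed = 42, squeeze = 0.15) {
  st <- initialize_chain(params, seed = seed)
  noise <- withr::with_seed(seed + 1,
                            matrix(rnorm(3 * params$N, 0, 0.5), params$N, 3))
  chain_state(st$positions * squeeze + noise)
}

# single-bead parameter set (low-level constructor; derive_parameters needs N >= 2)
single_bead_params <- chain_parameters(
  N = 1, N_nt = 120, r_nt = 0.43, alpha = 0.847, r_eq = 43.7, chi = 0.5,
  k_spring = kB * 300 / (0.5e-9)^2, sigma = 5, omega = kB * 300,
  cutoff = 2^(1 / 6) * 5, zeta = 4.68546e-12, Q = -1.33e-19,
  D_target = 2.21e-12, mu_target = 2.84e-8, T = 300)

single_bead_state <- chain_state(matrix(0, 1, 3))

# central-difference gradient of the intramolecular energy (N), oracle for forces
numerical_forces <- function(state, params, h_nm = 1e-4, terms = c("bond", "ev")) {
  pos <- state$positions
  out <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) for (ax in 1:3) {
    pp <- pos; pp[i, ax] <- pos[i, ax] + h_nm
    pm <- pos; pm[i, ax] <- pos[i, ax] - h_nm
    out[i, ax] <- -(potential_energy(chain_state(pp), params, terms) -
                    potential_energy(chain_state(pm), params, terms)) /
                  (2 * h_nm * 1e-9)
  }
  out
}

# plain duct geometry (no reservoirs, degenerate pore) for field validation
duct_geometry <- function(L = 1000, w = 200, h = 100) {
  channel_geometry(reservoir_dims = c(0, 0, 0), channel_length = L,
                   channel_width = w, channel_height = h, pore_length = L / 5,
                   pore_width = w, pore_height = h, pore_start_x = 2 * L / 5,
                   electrode_potentials = c(-0.4, 0.4), electrode_offset = 0)
}
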