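test_that("the diffusion estimator is exact on linear MSD and recovers Brownian D", {
  # deterministic tracks x = sqrt(2 D t) per axis give msd = 6 D t exactly
  D0 <- 3e-12
  times <- seq(0, 1e-6, by = 1e-8)
  tracks <- lapply(1:2, function(i) {
    disp <- sqrt(2 * D0 * times) * 1e9
    structure(list(times = times, com = cbind(disp, disp, disp),
                   mode = "free", dt = 1e-8, output_stride = 1L),
              class = "trajectory")
  })
  est <- estimate_diffusion(tracks, time_average = FALSE, max_lag_frac = 1)
  expect_equal(est$D, D0, tolerance = 1e-9)
  # generate-and-recover on exact Brownian tracks
  brown <- make_fixture("synthetic_brownian", seed = 8, size = 40, D = 2.21e-12)
  estb <- estimate_diffusion(brown)
  expect_lt(abs(estb$D - 2.21e-12), 2.5 * 2.21e-12 * 0.25 / sqrt(40))
  expect_error(estimate_diffusion(brown[1]), "at least 2")
})

test_that("the mobility estimator is exact on deterministic drift and unbiased", {
  mu0 <- 2.84e-8
  E <- 1e6
  times <- seq(0, 1e-6, by = 1e-8)
  tracks <- lapply(1:2, function(i)
    structure(list(times = times, com = cbind(mu0 * E * times * 1e9, 0, 0),
                   mode = "uniform", dt = 1e-8, output_stride = 1L),
              class = "trajectory"))
  est <- estimate_mobility(tracks, E)
  expect_equal(est$mu, mu0, tolerance = 1e-12)
  # noisy drift recovery within ~2 standard errors
  drift <- make_fixture("synthetic_drift", seed = 12, size = 30, D = 2.21e-12,
                        v = mu0 * E)
  estd <- estimate_mobility(drift, E)
  expect_lt(abs(estd$mu - mu0), 3 * estd$stderr + 1e-12)
})

test_that("pore occupancy counts beads, re-zeroes the clock and flags non-entry", {
  geo <- preset_geometry("scaled")
  px0 <- geo$pore_start_x
  p <- scaled_params
  mk_traj <- function(snaps) {
    structure(list(times = (seq_along(snaps) - 1) * 1e-8,
                   com = t(vapply(snaps, colMeans, numeric(3))),
                   snapshots = snaps, mode = "translocation", dt = 1e-8,
                   output_stride = 1L, snapshot_stride = 1L, geometry = geo),
              class = "trajectory")
  }
  # all beads before the pore: empty after re-zeroing
  before <- lapply(1:5, function(i) cbind(seq(-200, -10, length.out = 10), 0, 0))
  occ0 <- pore_occupancy(mk_traj(before), geo)
  expect_false(occ0$entered)
  expect_length(occ0$n_pore, 0)
  # straight chain spanning the pore at bond spacing r_eq: floor(200/43.7)
  # scaled: floor(20 / 4.37) + boundary -> 4-5 beads
  spanning <- cbind(seq(0, by = p$r_eq, length.out = p$N) + 90, 0, 0)
  snaps <- list(before[[1]], spanning, spanning, before[[1]])
  occ <- pore_occupancy(mk_traj(snaps), geo)
  expect_true(occ$entered)
  expect_equal(occ$times[1], 0)
  expect_true(all(occ$n_pore[1:2] %in% 4:5))
  # a hairpin doubles the single-strand count
  hair <- rbind(cbind(seq(90, by = p$r_eq / sqrt(2), length.out = p$N / 2), 1, 0),
                cbind(seq(by = -p$r_eq / sqrt(2), length.out = p$N / 2,
                          from = 90 + (p$N / 2 - 1) * p$r_eq / sqrt(2)), -1, 0))
  occ_h <- pore_occupancy(mk_traj(list(hair, hair)), geo)
  expect_gt(occ_h$n_pore[1], 1.7 * max(occ$n_pore))
})

test_that("fold-state histogram recovers constructed mixtures", {
  p <- scaled_params
  b <- 5L
  # pure baseline: one peak, all frames unfolded
  pure <- structure(list(times = 0:99 * 1e-8, n_pore = rep(b, 100),
                         pore_interval = c(100, 120), entered = TRUE),
                    class = "occupancy_series")
  fh <- fold_state_histogram(pure, p)
  expect_equal(fh$baseline, b)
  expect_equal(unname(fh$distribution["0"]), 1)
  expect_true(all(fh$labels == "unfolded"))
  # 70/30 mixture at b and 2b recovered within 2 percent at 1e4 frames
  mix <- make_fixture("occupancy_mixture", seed = 4, size = 1e4,
                      baseline = b, weights = c(0.7, 0.3))
  fm <- fold_state_histogram(mix, p)
  expect_equal(fm$baseline, b)
  expect_equal(unname(fm$distribution["0"]), 0.7, tolerance = 0.03)
  expect_equal(unname(fm$distribution["1"]), 0.3, tolerance = 0.07)
  expect_equal(sum(fm$distribution), 1)
  # permutation invariance over input ordering
  two <- list(pure, mix)
  expect_equal(fold_state_histogram(two, p)$distribution,
               fold_state_histogram(rev(two), p)$distribution)
  expect_error(fold_state_histogram(list(), p), "empty")
})

test_that("velocity profiles recover constructed tracks", {
  # constant-velocity track: flat profile at that velocity
  v0 <- 0.1 # m/s
  times <- seq(0, 2e-6, by = 1e-8)
  tr <- structure(list(times = times, com = cbind(v0 * times * 1e9, 0, 0),
                       mode = "translocation", dt = 1e-8, output_stride = 1L),
                  class = "trajectory")
  prof <- com_velocity_profile(tr, bin_width = 20, xlim = c(0, 300))
  expect_lt(max(abs(prof$v_G[prof$n > 0] - v0), na.rm = TRUE) / v0, 1e-9)
  # bins beyond the track are gaps (NA), never interpolated
  expect_true(all(is.na(prof$v_G[prof$x_G > 210])))
  # linear-in-x velocity (exponential track): recovered slope
  a <- 2e6 # 1/s
  x0 <- 10 # nm
  tr2 <- structure(list(times = times, com = cbind(x0 * exp(a * times), 0, 0),
                        mode = "translocation", dt = 1e-8, output_stride = 1L),
                   class = "trajectory")
  prof2 <- com_velocity_profile(tr2, bin_width = 10, xlim = c(10, 200))
  keep <- prof2$n > 2
  fit <- lm(v_G ~ x_G, data = prof2[keep, ])
  expect_equal(unname(coef(fit)[2]) * 1e9, a, tolerance = 0.02)
})

test_that("the reduced theory reproduces the tabulated terminal velocities", {
  p <- paper_params
  # 30x30 row: E_channel 8.2e4, E_pore 2.7e6, N_pore 6.48 -> 3.54 mm/s
  v30 <- theory_terminal_velocity(p, theory_inputs(E_channel = 8.2e4,
                                                   E_pore = 2.7e6,
                                                   N_pore_mean = 6.48))
  expect_equal(v30 * 1e3, 3.54, tolerance = 0.01 / 3.54)
  # 40x40 row -> 4.41 mm/s
  v40 <- theory_terminal_velocity(p, theory_inputs(E_channel = 1.2e5,
                                                   E_pore = 2.2e6,
                                                   N_pore_mean = 6.81))
  expect_equal(v40 * 1e3, 4.41, tolerance = 0.01 / 4.41)
  # uniform-field limit reduces exactly to mu E
  E <- 1e6
  vu <- theory_terminal_velocity(p, theory_inputs(E_channel = E, E_pore = E,
                                                  N_pore_mean = 6))
  expect_equal(vu, p$mu_target * E, tolerance = 1e-12)
  expect_error(theory_terminal_velocity(p, theory_inputs(N_pore_mean = 500)),
               "exceeds")
})

test_that("the entry-slope formula is linear and matches direct arithmetic", {
  p <- paper_params
  ti <- theory_inputs(E_channel = 8.2e4, dN_dx = 1.30e9)
  s30 <- theory_entry_slope(p, ti)
  expect_equal(s30, abs(p$Q) * 8.2e4 * 1.30e9 / (400 * p$zeta))
  expect_equal(s30, 7.57e3, tolerance = 0.01)
  expect_equal(theory_entry_slope(p, theory_inputs(E_channel = 0, dN_dx = 1e9)), 0)
  ti2 <- theory_inputs(E_channel = 8.2e4, dN_dx = 2 * 1.30e9)
  expect_equal(theory_entry_slope(p, ti2), 2 * s30)
})
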