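test_that("derived parameters reproduce the printed physical constants", {
  p <- paper_params
  # r_eq = alpha r_nt N_nt / N = 43.7 nm
  expect_equal(p$r_eq, 0.847 * 0.43 * 48000 / 400)
  expect_equal(p$r_eq, 43.7, tolerance = 2e-4)
  # zeta = kB T / (N D); printed to three digits as 4.68e-12 kg/s
  expect_equal(p$zeta, kB * 300 / (400 * 2.21e-12))
  expect_equal(p$zeta, 4.68e-12, tolerance = 2.5e-3)
  # Q = -mu kB T / (N D) = -0.83 e
  expect_equal(p$Q / e_charge, -0.83, tolerance = 1e-3)
  # k_spring = kB T / chi^2 with chi = 0.1 sigma = 0.5 nm
  expect_equal(p$k_spring, kB * 300 / (0.5e-9)^2)
  expect_equal(p$chi, 0.1 * p$sigma)
  expect_gt(p$cutoff, p$sigma)
  expect_gt(p$omega, 0)
})

test_that("derive_parameters is pure and validates its inputs", {
  a <- derive_parameters(N = 400)
  b <- derive_parameters(N = 400)
  expect_identical(a, b)
  expect_error(derive_parameters(N = 1), "N")
  expect_error(derive_parameters(N = 400, D_target = -1), "D_target")
  expect_error(derive_parameters(N = 400, T = 0), "T")
  expect_error(chain_parameters(N = 2, N_nt = 240, r_nt = 0.43, alpha = 0.847,
                                r_eq = 43.7, chi = 0.5, k_spring = 1e-2,
                                sigma = 5, omega = 4e-21, cutoff = 4, # < sigma
                                zeta = 5e-12, Q = -1e-19, D_target = 1e-12,
                                mu_target = 1e-8, T = 300),
               "cutoff")
})

test_that("bond forces obey Hooke's law and Newton's third law", {
  p <- small_params
  # all bonds at r_eq: zero force
  pos <- cbind(seq(0, by = p$r_eq, length.out = p$N), 0, 0)
  f <- bond_forces(chain_state(pos), p)
  expect_equal(max(abs(f)), 0)
  # two beads stretched by delta: equal and opposite restoring force k*delta
  delta <- 0.8 # nm
  p2 <- derive_parameters(N = 2, N_nt = 24, r_nt = 0.43, alpha = 0.847,
                          sigma = 5, D_target = 2.21e-12 * 200)
  st2 <- chain_state(rbind(c(0, 0, 0), c(p2$r_eq + delta, 0, 0)))
  f2 <- bond_forces(st2, p2)
  expect_equal(f2[1, 1], p2$k_spring * delta * 1e-9, tolerance = 1e-12)
  expect_equal(f2[1, ], -f2[2, ])
  # random chain: forces sum to zero
  st <- crumpled_chain(p)
  expect_lt(max(abs(colSums(bond_forces(st, p)))), 1e-18)
  # coincident bonded beads are degenerate
  expect_error(bond_forces(chain_state(matrix(0, 2, 3)), p2), "degenerate")
})

test_that("analytic forces match the numerical energy gradient", {
  p <- small_params
  st <- crumpled_chain(p, seed = 7)
  fb <- bond_forces(st, p)
  fe <- excluded_volume_forces(st, p)
  fn <- numerical_forces(st, p)
  expect_gt(max(abs(fe)), 0) # the squeezed chain has interacting pairs
  scale <- max(abs(fn))
  expect_lt(max(abs(fb + fe - fn)) / scale, 1e-5)
})

test_that("excluded volume is WCA: repulsive, truncated, bonded pairs excluded", {
  p <- small_params
  # pair at the cutoff: zero force and energy
  p3 <- derive_parameters(N = 3, N_nt = 36, r_nt = 0.43, alpha = 0.847,
                          sigma = 5, D_target = 2.21e-12 * 133)
  r3 <- p3$r_eq
  st <- chain_state(rbind(c(0, 0, 0), c(r3 * 0.6, r3 * 0.8, 0), c(p3$cutoff, 0, 0)))
  f <- excluded_volume_forces(st, p3)
  expect_equal(f[1, ], c(0, 0, 0)) # partner (bead 3) exactly at cutoff
  expect_equal(potential_energy(st, p3, terms = "ev"), 0)
  # pair at separation sigma: energy omega, repulsive force
  st2 <- chain_state(rbind(c(0, 0, 0), c(r3 * 0.6, r3 * 0.8, 0), c(p3$sigma, 0, 0)))
  expect_equal(potential_energy(st2, p3, terms = "ev"), p3$omega, tolerance = 1e-10)
  f2 <- excluded_volume_forces(st2, p3)
  expect_lt(f2[1, 1], 0) # bead 1 pushed towards -x, away from bead 3
  expect_equal(f2[1, ], -f2[3, ])
  # bonded neighbours never interact through this term
  st3 <- chain_state(rbind(c(0, 0, 0), c(1, 0, 0), c(100, 0, 0)))
  expect_equal(max(abs(excluded_volume_forces(st3, p3))), 0)
  # pairwise antisymmetry on a random chain: total force is zero
  st4 <- crumpled_chain(p, seed = 9)
  f4 <- excluded_volume_forces(st4, p)
  expect_lt(max(abs(colSums(f4))) / max(abs(f4)), 1e-12)
})

test_that("cell-list and all-pairs excluded-volume forces are bit-identical", {
  for (seed in 1:5) {
    st <- crumpled_chain(small_params, seed = seed)
    expect_identical(excluded_volume_forces(st, small_params, "cell"),
                     excluded_volume_forces(st, small_params, "all_pairs"))
  }
  st400 <- crumpled_chain(paper_params, seed = 3)
  expect_identical(excluded_volume_forces(st400, paper_params, "cell"),
                   excluded_volume_forces(st400, paper_params, "all_pairs"))
})

test_that("generated chains have exact bonds, the right contour and coil size", {
  p <- paper_params
  st <- initialize_chain(p, seed = 1)
  b <- sqrt(rowSums((st$positions[-1, ] - st$positions[-p$N, ])^2))
  expect_lt(max(abs(b - p$r_eq)) / p$r_eq, 0.01)
  expect_equal(sum(b), (p$N - 1) * p$r_eq, tolerance = 1e-6)
  expect_equal(p$N * p$r_eq * 1e-3, 17.48, tolerance = 1e-3) # contour 17.48 um
  # reproducibility
  expect_identical(st$positions, initialize_chain(p, seed = 1)$positions)
  expect_false(identical(st$positions, initialize_chain(p, seed = 2)$positions))
  # centre of mass lands on the requested start point
  st2 <- initialize_chain(p, start = c(100, -50, 25), seed = 3)
  expect_equal(colMeans(st2$positions), c(100, -50, 25), ignore_attr = TRUE)
})

test_that("radius of gyration: point, dumbbell, rigid-motion invariance", {
  expect_equal(radius_of_gyration(chain_state(matrix(1:3, 1))), 0)
  d <- 7.3
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(d, 0, 0))), d / 2)
  st <- initialize_chain(small_params, seed = 5)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- st$positions %*% R + 10
  expect_equal(radius_of_gyration(st), radius_of_gyration(rot), tolerance = 1e-12)
})

test_that("chain parameters and configurations round-trip through files", {
  tmp <- withr::local_tempdir()
  pfile <- file.path(tmp, "params.yaml")
  write_chain_parameters(small_params, pfile)
  p2 <- read_chain_parameters(pfile)
  expect_equal(p2, small_params, tolerance = 1e-12)
  st <- initialize_chain(small_params, seed = 2)
  xyz <- file.path(tmp, "chain.xyz")
  write_xyz(st, xyz)
  lines <- readLines(xyz)
  expect_equal(as.integer(lines[1]), small_params$N)
  expect_match(lines[2], "t = ")
  csv <- file.path(tmp, "chain.csv")
  write_chain_csv(st, csv)
  df <- read.csv(csv)
  expect_equal(df$x_nm, unname(st$positions[, 1]))
})
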