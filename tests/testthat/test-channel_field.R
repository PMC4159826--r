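test_that("geometry validation catches impossible configurations", {
  expect_error(channel_geometry(pore_width = 600), "cross-section")
  expect_error(channel_geometry(pore_start_x = 2100, pore_length = 200), "along x")
  geo <- preset_geometry("paper_30x30")
  expect_equal(geo$pore_start_x + c(0, geo$pore_length), c(1000, 1200))
  expect_equal(geo$channel_height, geo$pore_height)
})

test_that("the mask discretizes reservoirs, channel and pore correctly", {
  geo <- preset_geometry("paper_30x30")
  grid <- build_geometry(geo, spacing = 10)
  # 3 x 3 nodes across the 30 nm pore at 10 nm spacing
  i_pore <- which(grid$x > 1000 & grid$x < 1200)
  cs <- grid$mask[i_pore[5], , ]
  expect_equal(sum(cs > 0), 9)
  # channel cross-section much wider, same height
  i_chan <- which(grid$x > 0 & grid$x < 1000)
  expect_gt(sum(grid$mask[i_chan[5], , ] > 0), 100)
  # every x-plane is populated (connected along x)
  expect_true(all(apply(grid$mask > 0, 1, any)))
  # degenerate pore (same cross-section as channel) gives a straight duct mask
  duct <- duct_geometry()
  gd <- build_geometry(duct, spacing = 20)
  counts <- apply(gd$mask > 0, 1, sum)
  expect_equal(length(unique(counts)), 1)
  # resolution / divisibility preconditions
  expect_error(build_geometry(geo, spacing = 20), "resolve the pore")
  expect_error(build_geometry(duct_geometry(L = 1010), spacing = 20), "divide")
})

test_that("a uniform duct yields a linear potential and the exact field", {
  gd <- solve_laplace(build_geometry(duct_geometry(), spacing = 20))
  prof <- potential_profile_on_axis(gd)
  fit <- lm(phi ~ x, data = prof)
  expect_lt(max(abs(resid(fit))), 1e-10)
  # field = dV / L to discretization error (electrode planes sit half a cell in)
  E <- abs(unname(coef(fit)[2])) * 1e9
  expect_equal(E, 0.8 / 1000e-9, tolerance = 0.03)
  # profile spans the electrode potentials and is monotone
  expect_true(all(diff(prof$phi) > 0))
  expect_equal(range(prof$phi), c(-0.4, 0.4), tolerance = 0.05)
})

test_that("a two-segment duct matches the 1-D series-resistor oracle", {
  # segment areas A1 = 200x100, A2 = 100x100 -> field ratio A1/A2 = 2
  seg <- channel_geometry(reservoir_dims = c(0, 0, 0), channel_length = 1000,
                          channel_width = 200, channel_height = 100,
                          pore_length = 500, pore_width = 100, pore_height = 100,
                          pore_start_x = 500, electrode_potentials = c(-0.4, 0.4),
                          electrode_offset = 0)
  gs <- solve_laplace(build_geometry(seg, spacing = 10))
  E1 <- abs(electric_force_at(c(250, 5, 5), gs, 1)[1])
  E2 <- abs(electric_force_at(c(750, 5, 5), gs, 1)[1])
  expect_equal(E2 / E1, 2, tolerance = 0.05)
  # current conservation ties the two segments together
  cur <- cross_section_current(gs)$current
  expect_lt(sd(cur) / abs(mean(cur)), 1e-3)
})

test_that("the solution is gauge invariant and deterministic", {
  seg <- duct_geometry(L = 600, w = 100, h = 100)
  g1 <- solve_laplace(build_geometry(seg, spacing = 20))
  seg2 <- seg
  seg2$electrode_potentials <- seg$electrode_potentials + 0.25
  g2 <- solve_laplace(build_geometry(seg2, spacing = 20))
  expect_lt(max(abs(g1$gradient$x - g2$gradient$x)), 1e-4 * max(abs(g1$gradient$x)))
  g1b <- solve_laplace(build_geometry(seg, spacing = 20))
  expect_identical(g1$values, g1b$values)
})

test_that("interpolated forces: exact on linear potentials, first-order on quadratics", {
  gd <- solve_laplace(build_geometry(duct_geometry(), spacing = 20))
  Q <- -1.33e-19
  E <- abs(diff(potential_profile_on_axis(gd)$phi[1:2])) /
    (gd$spacing * 1e-9) # V/m along +x
  f <- electric_force_at(c(500, 0, 0), gd, Q)
  expect_equal(f[1], -Q * E, tolerance = 1e-6)
  expect_lt(max(abs(f[2:3])), 1e-20)
  # Q = 0 gives zero force
  expect_equal(electric_force_at(c(500, 0, 0), gd, 0), c(0, 0, 0))
  # quadratic test potential: phi = a x^2 (in nm^2), grad = 2 a x
  gq <- build_geometry(duct_geometry(), spacing = 20)
  a <- 1e-4
  xs <- array(rep(gq$x, prod(gq$dims[2:3])), dim = gq$dims)
  gq$values <- a * xs^2
  gq$gradient <- poredyn:::.grid_gradient(gq$values, gq$mask, gq$spacing)
  gq$solved <- TRUE
  set.seed(1)
  pts <- cbind(runif(200, 100, 900), runif(200, -80, 80), runif(200, -30, 30))
  fq <- electric_force_at(pts, gq, -1)
  expected <- 2 * a * pts[, 1] * 1e9 # d(phi)/dx in V/m
  expect_lt(max(abs(fq[, 1] - expected)) / max(abs(expected)), 0.02)
  # positions far outside the fluid raise a domain error
  expect_error(electric_force_at(c(500, 500, 500), gd, Q), "outside")
})

test_that("shrinking the pore concentrates and strengthens the field", {
  solves <- lapply(c("reduced_50x50", "reduced_40x40", "reduced_30x30"),
                   function(nm) solve_laplace(build_geometry(preset_geometry(nm),
                                                             spacing = 10),
                                              tolerance = 1e-8))
  Ep <- vapply(solves, function(g) field_summary(g)$E_pore, 0)
  expect_true(all(diff(Ep) > 0)) # 50x50 < 40x40 < 30x30
  expect_true(all(Ep > 1e6 & Ep < 1e7)) # order 1e6 V/m
  # steepest axial gradient falls inside the pore interval
  g30 <- solves[[3]]
  prof <- potential_profile_on_axis(g30)
  imax <- which.max(abs(diff(prof$phi)))
  xmax <- (prof$x[imax] + prof$x[imax + 1]) / 2
  geo <- g30$geometry
  expect_gte(xmax, geo$pore_start_x)
  expect_lte(xmax, geo$pore_start_x + geo$pore_length)
  # flux conservation across every cross-section
  cur <- cross_section_current(g30)$current
  expect_lt(sd(cur) / abs(mean(cur)), 1e-3)
})

test_that("halving the spacing changes the pore-centre field by under 5 percent", {
  geo <- preset_geometry("reduced_40x40")
  E1 <- field_summary(solve_laplace(build_geometry(geo, spacing = 20),
                                    tolerance = 1e-8))$E_pore
  E2 <- field_summary(solve_laplace(build_geometry(geo, spacing = 10),
                                    tolerance = 1e-8))$E_pore
  expect_lt(abs(E1 - E2) / E2, 0.05)
})

test_that("grids export to VTK and round-trip through artifacts", {
  tmp <- withr::local_tempdir()
  gd <- solve_laplace(build_geometry(duct_geometry(L = 400, w = 100, h = 100),
                                     spacing = 20))
  vtk <- file.path(tmp, "field.vtk")
  write_grid_vtk(gd, vtk)
  head <- readLines(vtk, n = 5)
  expect_match(head[1], "vtk DataFile")
  expect_match(head[5], sprintf("DIMENSIONS %d %d %d", gd$dims[1], gd$dims[2],
                                gd$dims[3]))
  rds <- file.path(tmp, "field.rds")
  save_artifact(gd, rds)
  expect_equal(read_artifact(rds), gd)
})
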