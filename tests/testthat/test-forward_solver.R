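test_that("diffusion coefficient evaluates 1/(3(mu_s' + mu_a))", {
  expect_equal(diffusion_coefficient(0, 1 / 3), 1)
  expect_equal(diffusion_coefficient(0.005, 0.5), 1 / (3 * 0.505))
  expect_equal(diffusion_coefficient(0.03, 3.0), 1 / (3 * 3.03))
  expect_error(diffusion_coefficient(0, 0), "positive")
  expect_error(diffusion_coefficient(-1, 0.5), "positive")
})

test_that("assembled systems are symmetric, real at DC, linear in D", {
  mesh <- build_disk_mesh(8, 80)
  co <- homogeneous_coeffs(mesh, 0.012, 1.1)
  sys <- assemble_fd_system(mesh, co, 70)
  expect_equal(max(abs(sys$Sr - Matrix::t(sys$Sr))), 0)
  expect_equal(max(abs(sys$Si - Matrix::t(sys$Si))), 0)
  sys0 <- assemble_fd_system(mesh, co, 0)
  expect_equal(max(abs(sys0$Si)), 0)

  # stiffness is linear in D: equal D-increments give equal matrix increments
  mk <- function(scale) {
    s <- 0.012 + 1.1
    # same mu_a, total attenuation scaled so that D -> scale * D
    structure(list(mu_a = co$mu_a, mu_s = rep(s / scale - 0.012, length(co$mu_a))),
              class = "dot_coeffs")
  }
  A1 <- assemble_fd_system(mesh, mk(1), 0)$Sr
  A2 <- assemble_fd_system(mesh, mk(2), 0)$Sr
  A3 <- assemble_fd_system(mesh, mk(3), 0)$Sr
  expect_lt(max(abs((A3 - A2) - (A2 - A1))), 1e-12 * max(abs(A2)))
  expect_gt(max(abs(A2 - A1)), 0)
  expect_error(assemble_fd_system(mesh, list(mu_a = 1, mu_s = 1), 10), "node count")
})

test_that("homogeneous-disk fields honor mirror symmetry and attenuation", {
  mesh <- build_disk_mesh(16, 100)
  co <- homogeneous_coeffs(mesh)
  probe <- probe_geometry()
  sys <- assemble_fd_system(mesh, co, 50)
  fields <- solve_sources(sys, probe, mesh, co)
  # reflection y -> -y maps the mesh onto itself and fixes source 1 (angle 0)
  n <- mesh$n_rings
  map <- seq_len(nrow(mesh$node_coords))
  for (k in seq_len(n)) {
    off <- 2L + 3L * k * (k - 1L)
    j <- 0:(6L * k - 1L)
    map[off + j] <- off + ((6L * k - j) %% (6L * k))
  }
  f1 <- fields[, 1]
  expect_lt(max(Mod(f1 - f1[map])) / max(Mod(f1)), 1e-8)
  # attenuation: nearest detector reads more than the farthest
  meas <- read_detectors(fields, probe, mesh, 50)
  expect_gt(meas$log_amplitude[1, 1], meas$log_amplitude[1, 8])
})

test_that("adjoint reciprocity of the symmetric system holds to 1e-6", {
  mesh <- build_disk_mesh(16, 90)
  co <- homogeneous_coeffs(mesh, 0.008, 0.9)
  probe <- probe_geometry()
  sys <- assemble_fd_system(mesh, co, 60)
  B <- dotbench:::source_loads(mesh, probe, 1 / 0.9)
  x <- dotbench:::solve_complex(sys, B)
  worst <- 0
  for (i in c(1, 4)) for (j in c(2, 9, 13)) {
    yij <- sum(B[, j] * x[, i])
    yji <- sum(B[, i] * x[, j])
    worst <- max(worst, Mod(yij - yji) / Mod(yij))
  }
  expect_lt(worst, 1e-6)
})

test_that("detector readout has the contracted shape and phase conventions", {
  mesh <- build_disk_mesh(16, 100)
  ph <- phantom(100, 50, 0.01, 1)
  meas <- forward_measure(ph, mesh)
  expect_identical(dim(meas$log_amplitude), c(16L, 15L))
  expect_identical(dim(meas$phase_lag), c(16L, 15L))
  expect_true(all(is.finite(meas$log_amplitude)))
  expect_true(all(meas$phase_lag >= 0 & meas$phase_lag < 2 * pi))
  # phase lag nondecreasing with source-detector chord distance
  chord <- 2 * 50 * sin(pi * (1:15) / 16)
  ord <- order(chord)
  expect_true(all(diff(meas$phase_lag[1, ord]) >= -1e-9))
  # DC drive: no phase
  ph0 <- phantom(100, 0, 0.01, 1)
  m0 <- forward_measure(ph0, mesh)
  expect_equal(max(abs(m0$phase_lag)), 0)
})

test_that("2-D analytic oracle: DC limit, attenuation, K0 implementation", {
  v0 <- analytic_infinite_medium(0.01, 1, 0, 10)
  expect_equal(Im(v0), 0, tolerance = 1e-12)
  D <- diffusion_coefficient(0.01, 1)
  expect_equal(Re(v0), besselK(10 * sqrt(0.01 / D), 0) / (2 * pi * D))
  expect_lt(Mod(analytic_infinite_medium(0.01, 1, 50, 20)),
            Mod(analytic_infinite_medium(0.01, 1, 50, 10)))
  # complex K0 agrees with base besselK on the real axis across both branches
  z <- c(0.3, 1, 3, 7.5, 8.5, 15)
  expect_equal(Re(dotbench:::besselK0_complex(z)), besselK(z, 0), tolerance = 1e-7)
  expect_equal(max(abs(Im(dotbench:::besselK0_complex(z)))), 0, tolerance = 1e-12)
})

test_that("FEM matches the infinite-medium oracle near an interior source", {
  # large homogeneous disk, unit load at the center node, field at 10 mm
  mesh <- build_disk_mesh(24, 150)
  co <- homogeneous_coeffs(mesh, 0.01, 1)
  sys <- assemble_fd_system(mesh, co, 50)
  b <- matrix(0 + 0i, nrow(mesh$node_coords), 1)
  b[1, 1] <- 1
  x <- dotbench:::solve_complex(sys, b)
  loc <- dotbench:::locate_points(mesh, matrix(c(10, 0), 1))
  fem <- sum(x[mesh$elements[loc$element[1], ], 1] * loc$bary[1, ])
  oracle <- analytic_infinite_medium(0.01, 1, 50, 10)
  expect_lt(abs(Mod(fem) - Mod(oracle)) / Mod(oracle), 0.05)
  expect_lt(abs(Arg(fem) - Arg(oracle)), 0.01)
})

test_that("boundary measurements converge under mesh refinement", {
  ph <- phantom(100, 30, 0.01, 1)
  la <- lapply(c(8, 16, 32), function(n) {
    forward_measure(ph, build_disk_mesh(n, 100))$log_amplitude
  })
  dcoarse <- median(abs(la[[2]] - la[[1]]))
  dfine <- median(abs(la[[3]] - la[[2]]))
  expect_lt(dfine, dcoarse)
})

test_that("probe geometry validates fiber placement on the mesh", {
  expect_error(dotbench:::fiber_nodes(build_disk_mesh(5, 100), probe_geometry(16)),
               "fibers")
  fn <- dotbench:::fiber_nodes(build_disk_mesh(16, 100), probe_geometry(16))
  expect_length(unique(fn), 16)
})
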