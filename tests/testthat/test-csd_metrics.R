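test_that("masked image MSE follows its definition", {
  X <- matrix(1, 4, 4); Y <- X
  expect_equal(mse_image(X, Y), 0)
  expect_equal(mse_image(X + 0.1, Y), 0.01)
  m <- matrix(FALSE, 4, 4); m[1, 1] <- m[2, 2] <- TRUE
  X2 <- Y; X2[1, 1] <- Y[1, 1] + 1; X2[2, 2] <- Y[2, 2] + 3
  expect_equal(mse_image(X2, Y, m), 5)
  expect_error(mse_image(X, matrix(1, 3, 3)), "shapes")
  expect_error(mse_image(X, Y, matrix(FALSE, 4, 4)), "mask")
})

test_that("resolution folding and classification follow the conventions", {
  expect_equal(dotbench:::fold_resolution(0.7), 0.7)
  expect_equal(dotbench:::fold_resolution(1.3), 0.7)
  expect_equal(dotbench:::fold_resolution(2.5), -0.5)
  expect_identical(classify_contrast(0.5, 8), "normal")
  expect_identical(classify_contrast(0.125, 8), "no contrast")
  expect_identical(classify_contrast(0.05, 8), "abnormal")
})

test_that("size and CSD compositions reproduce the worked resolution rows", {
  # simulated case A1675, absorption: R_cont 0.88, raw size 0.62 -> 0.74, 0.81
  rs <- compose_size_resolution(0.88, 0.62)
  expect_equal(round(rs, 2), 0.74)
  expect_equal(round(csd_resolution(0.88, 0.74), 2), 0.81)
  # simulated case A4483, absorption: 0.98 / 0.78 -> 0.87, 0.92
  expect_equal(round(compose_size_resolution(0.98, 0.78), 2), 0.87)
  expect_equal(round(csd_resolution(0.98, 0.87), 2), 0.92)
  # experimental case B2: scattering 0.48 / 0.23 -> 0.33; absorption CSD 0.48
  expect_equal(round(compose_size_resolution(0.48, 0.23), 2), 0.33)
  expect_equal(round(csd_resolution(0.73, 0.32), 2), 0.48)
  # negative branches (rows A4144, A3381, B1): unfolded-contrast substitution
  expect_lt(abs(compose_size_resolution(-0.02, -1.40) - -1.68), 0.01)
  expect_lt(abs(compose_size_resolution(0.74, -4.50) - -2.38), 0.01)
  expect_lt(abs(csd_resolution(-0.02, -1.68) - -1.84), 0.01)
  expect_lt(abs(compose_size_resolution(0.38, -0.04) - -0.26), 0.01)
  expect_lt(abs(csd_resolution(0.38, -0.26) - -0.65), 0.01)
  expect_lt(abs(compose_size_resolution(0.26, -0.17) - -0.55), 0.01)
  expect_lt(abs(csd_resolution(0.26, -0.55) - -0.98), 0.01)
  # perfect reconstruction fixed point
  expect_equal(compose_size_resolution(1, 1), 1)
  expect_equal(csd_resolution(1, 1), 1)
})

test_that("composition identities hold on nonnegative worked rows", {
  # (R_cont, Ro_size, R_size, R_csd) tuples from the worked resolution
  # tables (both coefficients, simulated and experimental cases); rows with
  # inconsistent printed values (A4617 mu_a, A6472) excluded
  rows <- list(
    c(0.63, 0.06, 0.19, 0.35), c(0.87, 0.39, 0.58, 0.71),
    c(0.88, 0.62, 0.74, 0.81), c(0.60, 0.28, 0.41, 0.50),
    c(0.85, 0.46, 0.63, 0.73), c(0.98, 0.78, 0.87, 0.92),
    c(0.86, 0.25, 0.46, 0.63), c(0.81, 0.51, 0.64, 0.72),
    c(0.56, 0.23, 0.36, 0.45), c(0.69, 0.36, 0.49, 0.58),
    c(0.78, 0.36, 0.53, 0.64), c(0.73, 0.14, 0.32, 0.48),
    c(0.48, 0.23, 0.33, 0.40), c(0.93, 0.63, 0.77, 0.84),
    c(0.98, 0.52, 0.72, 0.84))
  for (r in rows) {
    expect_lt(abs(compose_size_resolution(r[1], r[2]) - r[3]), 0.015)
    expect_lt(abs(csd_resolution(r[1], r[3]) - r[4]), 0.015)
  }
})

test_that("contrast and size resolutions behave on constructed images", {
  ph <- single_inclusion_phantom(80, 50, 0.01, 1, r = 14, roc = 16, th = 10,
                                 c_a = 3, c_s = 2)
  truth <- rasterize_truth(ph, 64)
  regions <- region_spec(ph, 64)
  # perfect reconstruction
  cr <- contrast_resolution(truth$mu_a_grid, truth$mu_a_grid, regions)
  expect_equal(cr$Ro_cont, 1)
  expect_equal(cr$R_cont, 1)
  sr <- size_resolution(truth$mu_a_grid, truth$mu_a_grid, regions, 1, 0.01)
  expect_equal(sr$Ro_size, 1)
  expect_equal(sr$R_size, 1)
  # flat-background reconstruction: zero size resolution
  flat <- truth$mu_a_grid; flat[truth$mask] <- 0.01
  sr0 <- size_resolution(flat, truth$mu_a_grid, regions, 0, 0.01)
  expect_equal(sr0$Ro_size, 0)
  expect_equal(sr0$R_size, 0)
  expect_equal(csd_resolution(0, 0), 0)
  # positive rescaling of both images leaves the ratio metrics unchanged
  cr5 <- contrast_resolution(5 * truth$mu_a_grid, 5 * truth$mu_a_grid, regions)
  expect_equal(cr5$R_cont, cr$R_cont)
  # region masks are disjoint
  expect_false(any(regions$inclusion_masks[[1]] & regions$background_mask))
})

test_that("evaluate_sample produces the full per-coefficient report", {
  ph <- single_inclusion_phantom(80, 50)
  truth <- rasterize_truth(ph, 64)
  rep1 <- evaluate_sample(truth, truth, ph)
  expect_false(rep1$homogeneous)
  expect_equal(rep1$table$R_cont, c(1, 1))
  expect_equal(rep1$table$R_size, c(1, 1))
  expect_equal(rep1$table$R_csd, c(1, 1))
  expect_identical(rep1$table$classification, c("normal", "normal"))
  expect_true(all(rep1$table$pass_T))
  # flat reconstruction: all size/CSD resolutions 0, fails T = 0.3
  flat <- truth
  flat$mu_a_grid[truth$mask] <- ph$mu_a0
  flat$mu_s_grid[truth$mask] <- ph$mu_s0
  rep0 <- evaluate_sample(flat, truth, ph)
  expect_equal(rep0$table$R_csd, c(0, 0))
  expect_false(any(rep0$table$pass_T))
  # homogeneous phantom: metrics undefined, flagged
  ph0 <- phantom(80, 50, 0.01, 1)
  rep2 <- evaluate_sample(rasterize_truth(ph0, 64), phantom = ph0)
  expect_true(rep2$homogeneous)
})
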