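test_that("disk mesh node/element counts follow the ring formulas", {
  for (n in c(1:8, 16L, 24L, 32L, 40L)) {
    m <- build_disk_mesh(n, 100)
    expect_identical(nrow(m$node_coords), 3L * n * n + 3L * n + 1L)
    expect_identical(nrow(m$elements), 6L * n * n)
    expect_identical(length(m$boundary_nodes), 6L * n)
  }
})

test_that("mesh geometry is consistent", {
  m <- build_disk_mesh(32, 100)
  a <- dotbench:::signed_areas(m$node_coords, m$elements)
  expect_true(all(a > 0))
  expect_lt(abs(sum(a) - pi * 50^2) / (pi * 50^2), 0.01)
  r_bnd <- sqrt(rowSums(m$node_coords[m$boundary_nodes, ]^2))
  expect_true(all(abs(r_bnd - 50) < 1e-9 * 100))
  # every node is used; element indices are in range
  expect_true(all(m$elements >= 1 & m$elements <= nrow(m$node_coords)))
  expect_identical(sort(unique(as.vector(m$elements))),
                   seq_len(nrow(m$node_coords)))
  expect_error(build_disk_mesh(0, 100), "positive")
  expect_error(build_disk_mesh(4, -1), "positive")
})

test_that("point location finds containing elements with exact barycentrics", {
  m <- build_disk_mesh(8, 60)
  set.seed(11)
  th <- runif(200, 0, 2 * pi); rr <- 29.8 * sqrt(runif(200))  # inside the hull
  pts <- cbind(rr * cos(th), rr * sin(th))
  loc <- dotbench:::locate_points(m, pts)
  expect_true(all(!is.na(loc$element)))
  rec <- sapply(seq_len(200), function(i) {
    v <- m$elements[loc$element[i], ]
    colSums(m$node_coords[v, ] * loc$bary[i, ])
  })
  expect_lt(max(abs(t(rec) - pts)), 1e-8)
})

test_that("stratified allocation reproduces the exact partition counts", {
  cnt <- table(allocate_inclusion_counts(10000))
  expect_identical(as.integer(cnt), c(100L, 4400L, 5500L))
  # largest-remainder rounding always returns exactly n labels
  for (n in c(1, 7, 99, 997)) {
    expect_length(allocate_inclusion_counts(n), as.integer(n))
  }
})

test_that("sampled phantoms respect ranges, containment and determinism", {
  rng <- default_ranges()
  set.seed(5)
  for (i in 1:200) {
    ph <- sample_phantom(rng)
    expect_gte(ph$diameter_mm, rng$diameter_mm[1])
    expect_lte(ph$diameter_mm, rng$diameter_mm[2])
    expect_gte(ph$mu_a0, rng$mu_a0[1]); expect_lte(ph$mu_a0, rng$mu_a0[2])
    expect_gte(ph$mu_s0, rng$mu_s0[1]); expect_lte(ph$mu_s0, rng$mu_s0[2])
    expect_lte(length(ph$inclusions), 2)
    for (inc in ph$inclusions) {
      expect_gte(inc$radius_mm, rng$radius_mm[1])
      expect_lte(inc$radius_mm, rng$radius_mm[2])
      expect_gte(inc$contrast_a, rng$contrast[1])
      expect_lte(inc$contrast_a, rng$contrast[2])
      expect_lte(inc$off_center_mm + inc$radius_mm, 0.95 * ph$diameter_mm / 2 + 1e-9)
    }
    if (length(ph$inclusions) == 2) {
      c1 <- dotbench:::inclusion_center(ph$inclusions[[1]])
      c2 <- dotbench:::inclusion_center(ph$inclusions[[2]])
      expect_gte(sqrt(sum((c1 - c2)^2)),
                 ph$inclusions[[1]]$radius_mm + ph$inclusions[[2]]$radius_mm)
    }
  }
  set.seed(42); p1 <- sample_phantom(rng)
  set.seed(42); p2 <- sample_phantom(rng)
  expect_identical(p1, p2)
  # marginal coverage sanity: empirical range spans > 95% of the design range
  set.seed(6)
  ds <- replicate(2000, sample_phantom(rng, n_inclusions = 0)$diameter_mm)
  expect_gt((max(ds) - min(ds)) / diff(rng$diameter_mm), 0.95)
  # forced partition
  expect_length(sample_phantom(rng, n_inclusions = 0)$inclusions, 0)
})

test_that("nodal coefficient painting matches brute-force disc membership", {
  mesh <- build_disk_mesh(12, 100)
  ph0 <- phantom(100, 50, 0.01, 1)
  co0 <- nodal_coefficients(ph0, mesh)
  expect_true(all(co0$mu_a == 0.01) && all(co0$mu_s == 1))

  ph <- phantom(100, 50, 0.01, 1, list(inclusion(100 / 8, 100 / 4, 30, 2, 3)),
                margin = 1)
  co <- nodal_coefficients(ph, mesh)
  cen <- dotbench:::inclusion_center(ph$inclusions[[1]])
  inside <- rowSums(sweep(mesh$node_coords, 2, cen)^2) <= (100 / 8)^2
  expect_identical(sum(co$mu_a > 0.01), sum(inside))
  expect_equal(unique(co$mu_a[inside]), 0.02)
  expect_equal(unique(co$mu_s[inside]), 3)
  expect_error(nodal_coefficients(ph, build_disk_mesh(12, 90)), "diameter")
})

test_that("overlapping inclusions resolve to the maximum contrast", {
  mesh <- build_disk_mesh(8, 100)
  ph <- phantom(100, 0, 0.01, 1,
                list(inclusion(20, 0, 0, 2, 2), inclusion(20, 5, 0, 5, 3)),
                margin = 1)
  co <- nodal_coefficients(ph, mesh)
  cen2 <- dotbench:::inclusion_center(ph$inclusions[[2]])
  both <- rowSums(mesh$node_coords^2) <= 400 &
    rowSums(sweep(mesh$node_coords, 2, cen2)^2) <= 400
  expect_true(all(co$mu_a[both] == 0.05))
})

test_that("rasterized truth draws exact discs and a diameter-free mask", {
  ph <- phantom(100, 50, 0.01, 1, list(inclusion(25, 0, 0, 4, 2)), margin = 1)
  img <- rasterize_truth(ph, 64)
  g <- image_grid(64, 100)
  # homogeneous region
  expect_true(all(img$mu_a_grid[!img$mask] == 0))
  # brute-force pixel count of the centered 16-pixel-radius disc
  Xc <- matrix(g$x, 64, 64, byrow = TRUE); Yc <- matrix(g$y, 64, 64)
  nref <- sum(Xc^2 + Yc^2 <= 25^2)
  expect_identical(sum(img$mu_a_grid > 0.01), nref)
  # mask identical across diameters
  expect_identical(image_grid(64, 60)$mask, image_grid(64, 150)$mask)
  # homogeneous phantom: constant on mask
  img0 <- rasterize_truth(phantom(80, 0, 0.02, 2), 64)
  expect_true(all(img0$mu_a_grid[img0$mask] == 0.02))
  # contrast kind bounded in [0, 1]
  imgc <- rasterize_truth(ph, 64, kind = "contrast", c_max = 8)
  expect_true(all(imgc$mu_a_grid >= 0 & imgc$mu_a_grid <= 1))
  expect_equal(max(imgc$mu_a_grid), 3 / 7)
})

test_that("rasterization is diameter-covariant", {
  # same relative geometry at two diameters -> identical pixel footprints
  p1 <- phantom(80, 0, 0.01, 1, list(inclusion(10, 20, 90, 2, 2)), margin = 1)
  p2 <- phantom(160, 0, 0.01, 1, list(inclusion(20, 40, 90, 2, 2)), margin = 1)
  i1 <- rasterize_truth(p1, 64); i2 <- rasterize_truth(p2, 64)
  expect_identical(i1$mu_a_grid > 0.01, i2$mu_a_grid > 0.01)
})

test_that("mesh and phantom exports write readable tables", {
  td <- withr::local_tempdir()
  m <- build_disk_mesh(3, 50)
  fs <- export_mesh(m, file.path(td, "m"))
  nd <- read.csv(fs[1])
  expect_identical(nrow(nd), nrow(m$node_coords))
  expect_identical(sum(nd$boundary), length(m$boundary_nodes))
  ph <- single_inclusion_phantom()
  f <- export_phantoms(list(ph), file.path(td, "cases.csv"))
  tab <- read.csv(f)
  expect_identical(names(tab),
                   c("CASE", "D", "f", "mu_a", "mu_s", "r", "r_oc",
                     "theta_oc", "c_a", "c_s"))
  expect_equal(tab$D, 80)
})
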