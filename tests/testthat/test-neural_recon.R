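test_that("architecture shape contracts hold across probe sizes", {
  for (Ns in c(8L, 16L)) {
    cfg <- tiny_config(Ns)
    m <- assemble_network(cfg, seed = 3)
    B <- 2L
    X <- array(rnorm(B * Ns * (Ns - 1) * 2), c(B, Ns * (Ns - 1), 2))
    aux <- matrix(runif(B * 2), B, 2)
    out <- nn_forward(m, X, aux, train = FALSE)
    # block B pools to exactly 16 units
    expect_identical(ncol(m$blockB$pooled), 16L)
    # block A emits 16 x n_sources features
    feat <- m$blockA$forward(X, aux, train = FALSE)
    expect_identical(dim(feat), c(B, 16L * Ns))
    # outputs: contrast images in [0, 1], strictly positive backgrounds
    expect_identical(dim(out$contrast), c(B, 64L, 64L, 2L))
    expect_identical(dim(out$background), c(B, 2L))
    expect_true(all(out$background > 0))
    expect_true(all(out$contrast >= 0 & out$contrast <= 1))
    # circular mask: outside pixels exactly zero
    for (ch in 1:2) {
      img <- out$contrast[1, , , ch]
      expect_true(all(img[!m$mask] == 0))
    }
  }
  expect_error(network_config(n_sources = 7), "even")
})

test_that("Q loss matches its hand-computed decomposition", {
  g <- 64L
  mask <- image_grid(g, 1)$mask
  truth <- list(contrast = array(0.2, c(1, g, g, 2)),
                background = matrix(c(0.01, 1), 1))
  # perfect prediction
  expect_equal(loss_Q(truth, truth), 0)
  # absorption background off by 0.01 with w_a = 100^2 -> exactly 1
  p1 <- truth; p1$background <- matrix(c(0.02, 1), 1)
  expect_equal(loss_Q(p1, truth), 1, tolerance = 1e-12)
  # both contrast channels off by 0.1 on every masked pixel -> 2 * 0.1^2
  p2 <- truth
  p2$contrast <- truth$contrast + 0.1
  expect_equal(loss_Q(p2, truth, mask = mask), 0.02, tolerance = 1e-12)
  # decomposition equals the sum of per-component masked MSEs
  set.seed(8)
  p3 <- list(contrast = array(runif(g * g * 2), c(1, g, g, 2)),
             background = matrix(c(0.013, 1.4), 1))
  w <- loss_weights(2, 3, 50, 7)
  expect_equal(loss_Q(p3, truth, w, mask),
               2 * mse_image(p3$contrast[1, , , 1], truth$contrast[1, , , 1], mask) +
                 3 * mse_image(p3$contrast[1, , , 2], truth$contrast[1, , , 2], mask) +
                 50 * (0.013 - 0.01)^2 + 7 * (1.4 - 1)^2,
               tolerance = 1e-12)
  expect_error(loss_Q(p3, list(contrast = truth$contrast,
                               background = matrix(1, 1, 3))), "mismatch")
})

test_that("compiled convolution kernels agree with the pure-R reference", {
  set.seed(5)
  for (shape in list(c(2, 9, 7, 3), c(1, 6, 6, 2))) {
    x <- array(rnorm(prod(shape)), shape)
    l <- dotbench:::conv2d_layer(shape[4], 5L)
    y <- l$forward(x, train = TRUE)
    expect_equal(y, dotbench:::conv2d_ref(x, l$params$W, l$params$b),
                 tolerance = 1e-12)
    # backward against finite differences of the R reference
    dy <- array(rnorm(length(y)), dim(y))
    dx <- l$backward(dy)
    lossx <- function(xx) sum(dotbench:::conv2d_ref(xx, l$params$W, l$params$b) * dy)
    for (k in sample(length(x), 3)) {
      h <- 1e-6
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      expect_equal((lossx(xp) - lossx(xm)) / (2 * h), dx[k], tolerance = 1e-6)
    }
  }
})

test_that("layer primitives backpropagate exact gradients", {
  set.seed(6)
  # dense
  d <- dotbench:::dense_layer(4, 3)
  x <- matrix(rnorm(8), 2, 4)
  y <- d$forward(x)
  dy <- matrix(rnorm(6), 2, 3)
  dx <- d$backward(dy)
  num <- function(f, arr, k, h = 1e-6) {
    a1 <- arr; a1[k] <- a1[k] + h; a2 <- arr; a2[k] <- a2[k] - h
    (f(a1) - f(a2)) / (2 * h)
  }
  fx <- function(xx) sum(d$forward(xx) * dy)
  expect_equal(num(fx, x, 3), dx[3], tolerance = 1e-6)
  # conv1d (strided, unpadded) on an odd shape
  c1 <- dotbench:::conv1d_layer(2L, 3L, kernel = 5L, stride = 5L, pad = 0L)
  x1 <- array(rnorm(2 * 15 * 2), c(2, 15, 2))
  y1 <- c1$forward(x1)
  expect_identical(dim(y1), c(2L, 3L, 3L))
  dy1 <- array(rnorm(length(y1)), dim(y1))
  dx1 <- c1$backward(dy1)
  f1 <- function(xx) sum(c1$forward(xx) * dy1)
  for (k in sample(length(x1), 4)) {
    expect_equal(num(f1, x1, k), dx1[k], tolerance = 1e-6)
  }
  # batch normalization (training mode, through the batch statistics)
  bn <- dotbench:::batchnorm_layer(3)
  xb <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  yb <- bn$forward(xb, train = TRUE)
  expect_equal(apply(matrix(yb, 20, 3), 2, mean), rep(0, 3), tolerance = 1e-10)
  dyb <- array(rnorm(length(yb)), dim(yb))
  dxb <- bn$backward(dyb)
  fb <- function(xx) sum(bn$forward(xx, train = TRUE) * dyb)
  for (k in sample(length(xb), 4)) {
    expect_equal(num(fb, xb, k), dxb[k], tolerance = 1e-5)
  }
})

test_that("full-network gradients agree with finite differences", {
  set.seed(7)
  cfg <- tiny_config(8L)
  m <- assemble_network(cfg, seed = 7)
  B <- 3
  X <- array(rnorm(B * 56 * 2), c(B, 56, 2))
  aux <- matrix(runif(B * 2), B, 2)
  tc <- array(runif(B * 64 * 64 * 2), c(B, 64, 64, 2))
  tb <- matrix(runif(B * 2) * rep(c(0.03, 3), each = B), B, 2)
  w <- loss_weights()
  truth <- list(contrast = tc, background = tb)
  lossfun <- function() loss_Q(nn_forward(m, X, aux, TRUE), truth, w, m$mask)
  pred <- nn_forward(m, X, aux, train = TRUE)
  gr <- dotbench:::loss_Q_grad(pred, truth, w, m$mask)
  dotbench:::nn_backward(m, gr$dcontrast, gr$dbackground)
  layers <- dotbench:::nn_all_layers(m)
  set.seed(99)
  for (trial in 1:25) {
    li <- sample(seq_along(layers), 1)
    l <- layers[[li]]
    if (!length(l$params)) next
    pn <- sample(names(l$params), 1)
    k <- sample(length(l$params[[pn]]), 1)
    h <- 1e-5
    orig <- l$params[[pn]][k]
    l$params[[pn]][k] <- orig + h; fp <- lossfun()
    l$params[[pn]][k] <- orig - h; fm <- lossfun()
    l$params[[pn]][k] <- orig
    fd <- (fp - fm) / (2 * h)
    an <- l$grads[[pn]][k]
    if (abs(fd) < 1e-6 && abs(an) < 1e-6) next
    # tolerance allows finite-difference kink noise from the piecewise
    # activations; systematic errors would be orders of magnitude larger
    expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 0.06)
  }
})

test_that("training declines, records history and selects an epoch", {
  set.seed(31)
  ds <- generate_dataset(24, seed = 31, n_rings = 8)
  cfg <- tiny_config(16L)
  m <- assemble_network(cfg, seed = 31)
  tr <- train_network(m, ds, training_config(epochs = 5, batch_size = 8,
                                             learning_rate = 1e-3, seed = 31))
  expect_identical(nrow(tr$history), 5L)
  expect_lte(tr$selected_epoch, 5L)
  expect_lt(tail(tr$history$train_Q, 1), tr$history$train_Q[1])
  expect_true(all(is.finite(tr$history$validation_Q)))
  # deterministic under the seed
  m2 <- assemble_network(cfg, seed = 31)
  tr2 <- train_network(m2, ds, training_config(epochs = 5, batch_size = 8,
                                               learning_rate = 1e-3, seed = 31))
  expect_equal(tr$history, tr2$history)
})

test_that("an overfit model recovers a homogeneous phantom within 20%", {
  ph <- phantom(90, 50, 0.015, 1.2)
  mesh <- build_disk_mesh(8, 90)
  meas <- forward_measure(ph, mesh)
  n <- 5L
  ds <- structure(list(
    inputs = array(rep(c(meas$log_amplitude, meas$phase_lag), each = n),
                   c(n, 16, 15, 2)),
    aux = matrix(rep(c(50, 90), each = n), n, 2),
    truth_contrast = array(0, c(n, 64, 64, 2)),
    truth_background = matrix(rep(c(0.015, 1.2), each = n), n, 2),
    split = factor(rep(c("train", "validation"), c(4, 1)),
                   levels = c("train", "validation")),
    phantoms = rep(list(ph), n),
    mask = image_grid(64, 1)$mask,
    params = list()), class = "dot_dataset")
  cfg <- tiny_config(16L)
  m <- assemble_network(cfg, seed = 12)
  tr <- train_network(m, ds, training_config(epochs = 150, batch_size = 4,
                                             learning_rate = 5e-3, seed = 12))
  img <- reconstruct_nn(tr, meas)
  expect_true(all(img$mu_a_grid[!img$mask] == 0))
  expect_true(all(img$mu_a_grid[img$mask] > 0))
  expect_lt(max(abs(img$mu_a_grid[img$mask] - 0.015)) / 0.015, 0.2)
  expect_lt(max(abs(img$mu_s_grid[img$mask] - 1.2)) / 1.2, 0.2)
})

test_that("models round-trip through save/load with identical predictions", {
  td <- withr::local_tempdir()
  ds <- generate_dataset(10, seed = 17, n_rings = 8)
  cfg <- tiny_config(16L)
  m <- assemble_network(cfg, seed = 17)
  tr <- train_network(m, ds, training_config(epochs = 2, batch_size = 5, seed = 17))
  meas <- measurement_set(ds$inputs[1, , , 1], ds$inputs[1, , , 2],
                          ds$aux[1, 1], ds$aux[1, 2])
  img1 <- reconstruct_nn(tr, meas)
  p <- file.path(td, "model.rds")
  save_model(tr, p)
  expect_true(file.exists(file.path(td, "model_config.json")))
  tr2 <- load_model(p)
  img2 <- reconstruct_nn(tr2, meas)
  expect_equal(img1, img2, tolerance = 1e-12)
  expect_identical(tr2$selected_epoch, tr$selected_epoch)
  # measurement shape guard
  bad <- measurement_set(matrix(0, 4, 3), matrix(0, 4, 3), 50, 90)
  expect_error(reconstruct_nn(tr2, bad), "shape")
})

test_that("two-path variant keeps the output contract", {
  cfg <- network_config(n_sources = 8, preset = "scaled",
                        blockB_channels = 4, blockA_widths = c(4, 6),
                        aux_embedding_size = 8, fc_hidden = 24,
                        unet_widths = c(3, 4, 5), two_path = TRUE)
  m <- assemble_network(cfg, seed = 2)
  X <- array(rnorm(2 * 56 * 2), c(2, 56, 2))
  out <- nn_forward(m, X, matrix(runif(4), 2, 2), train = FALSE)
  expect_identical(dim(out$contrast), c(2L, 64L, 64L, 2L))
  expect_length(m$unets, 2L)
})
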