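# Sensor-to-image network: a branching graph with a background-predictor
# path (block B: strided 1-D convolutions over the ring-probe data) and a
# contrast-image path (block A: 1-D convolutional domain transform with an
# encoder-decoder bottleneck gated by the auxiliary scalars, two fully
# connected layers to a masked initial 64x64x2 image, then a residual U-net).
# Final absolute images = contrast x broadcast background per channel.

#' Network configuration
#'
#' Shape-defining hyperparameters of the sensor-to-image network. The first
#' convolution of both paths has stride \code{n_detectors} (one stride per
#' source activation); block B pools to exactly 16 units; block A emits
#' 16 x \code{n_sources} features ahead of the fully connected image stage.
#' Width parameters are free design choices; \code{preset = "scaled"} picks a
#' narrow variant suitable for CPU-scale training runs.
#'
#' @param n_sources,n_detectors ring-probe shape (defaults 16 and 15).
#' @param grid_size output image resolution (64).
#' @param preset "default" or "scaled".
#' @param blockB_channels width of block B's first convolution.
#' @param blockA_widths two-stage widths of block A (e.g. c(16, 64)).
#' @param aux_embedding_size bottleneck gate width (128 by default).
#' @param fc_hidden hidden width of the image-forming dense stage.
#' @param fcB_hidden hidden width of the background head.
#' @param unet_widths per-level U-net widths (3 resolution levels).
#' @param two_path if TRUE, each coefficient channel gets its own U-net
#'   (variant exposed for the known same-contour limitation of the shared
#'   path); default FALSE.
#' @param c_max maximum contrast used to denormalize contrast images.
#' @param bg_scale per-channel output scale of the background head (1/mm);
#'   the softplus output is multiplied by it so both coefficients start and
#'   move on their physical scales (absorption is ~100x smaller than
#'   scattering).
#' @param aux_ranges min/max rows for the two auxiliary scalars (frequency
#'   MHz, diameter mm) used for min-max scaling.
#' @return a \code{dot_nn_config}.
#' @export
network_config <- function(n_sources = 16L, n_detectors = n_sources - 1L,
                           grid_size = 64L, preset = c("default", "scaled"),
                           blockB_channels = NULL, blockA_widths = NULL,
                           aux_embedding_size = NULL, fc_hidden = NULL,
                           fcB_hidden = 32L, unet_widths = NULL,
                           two_path = FALSE, c_max = 8,
                           bg_scale = c(0.02, 2),
                           aux_ranges = rbind(frequency_MHz = c(10, 100),
                                              diameter_mm = c(60, 150))) {
  preset <- match.arg(preset)
  if (n_sources %% 2L != 0L) stop("n_sources must be even (encoder halves the length)")
  def <- if (preset == "default") {
    list(blockB_channels = 16L, blockA_widths = c(16L, 64L),
         aux_embedding_size = 128L, fc_hidden = 1024L,
         unet_widths = c(32L, 64L, 128L))
  } else {
    list(blockB_channels = 8L, blockA_widths = c(8L, 16L),
         aux_embedding_size = 32L, fc_hidden = 256L,
         unet_widths = c(4L, 8L, 16L))
  }
  cfg <- list(n_sources = as.integer(n_sources),
              n_detectors = as.integer(n_detectors),
              grid_size = as.integer(grid_size), preset = preset,
              blockB_channels = as.integer(blockB_channels %||% def$blockB_channels),
              blockB_pooled = 16L,
              blockA_widths = as.integer(blockA_widths %||% def$blockA_widths),
              blockA_depth = 23L,
              aux_embedding_size = as.integer(aux_embedding_size %||% def$aux_embedding_size),
              fc_hidden = as.integer(fc_hidden %||% def$fc_hidden),
              fcB_hidden = as.integer(fcB_hidden),
              unet_widths = as.integer(unet_widths %||% def$unet_widths),
              two_path = isTRUE(two_path), c_max = c_max,
              bg_scale = bg_scale, aux_ranges = aux_ranges)
  if (length(cfg$blockA_widths) != 2 || length(cfg$unet_widths) != 3) {
    stop("blockA_widths must have 2 entries and unet_widths 3")
  }
  structure(cfg, class = "dot_nn_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# multiply (B, H, W, C) images by a (H, W) mask, broadcasting over batch/channel
mask_mul <- function(x, mask) {
  d <- dim(x)
  mv <- as.vector(mask)
  np <- d[2] * d[3]
  dim(x) <- c(d[1], np, d[4])
  mrep <- rep(mv, each = d[1])
  for (ch in seq_len(d[4])) {
    x[, , ch] <- matrix(x[, , ch], d[1], np) * mrep
  }
  dim(x) <- d
  x
}

## ---- block B: background predictor ----

make_blockB <- function(cfg) {
  Nd <- cfg$n_detectors
  L <- list(
    conv1 = conv1d_layer(2L, cfg$blockB_channels, kernel = Nd, stride = Nd, pad = 0L),
    act1 = act_layer("relu"),
    conv2 = conv1d_layer(cfg$blockB_channels, cfg$blockB_pooled, kernel = 3L),
    act2 = act_layer("relu"),
    gap = global_avg_pool1d(),
    fc1 = dense_layer(cfg$blockB_pooled + 2L, cfg$fcB_hidden),
    act3 = act_layer("relu"),
    fc2 = dense_layer(cfg$fcB_hidden, 2L),
    out = act_layer("softplus"))
  e <- new.env(parent = emptyenv())
  e$layers <- L
  bg_scale <- cfg$bg_scale
  e$forward <- function(x, aux, train = TRUE) {
    h <- L$act2$forward(L$conv2$forward(L$act1$forward(L$conv1$forward(x, train), train), train), train)
    p <- L$gap$forward(h, train)
    e$pooled <- p
    z <- cbind(p, aux)
    out <- L$out$forward(L$fc2$forward(L$act3$forward(L$fc1$forward(z, train), train), train), train)
    out * rep(bg_scale, each = nrow(out))
  }
  e$backward <- function(dy) {
    dy <- dy * rep(bg_scale, each = nrow(dy))
    dz <- L$fc1$backward(L$act3$backward(L$fc2$backward(L$out$backward(dy))))
    np <- ncol(e$pooled)
    dp <- dz[, seq_len(np), drop = FALSE]
    daux <- dz[, np + 1:2, drop = FALSE]
    dh <- L$gap$backward(dp)
    dx <- L$conv1$backward(L$act1$backward(L$conv2$backward(L$act2$backward(dh))))
    list(dx = dx, daux = daux)
  }
  e
}

## ---- block A: 1-D domain transform with gated bottleneck ----

make_blockA <- function(cfg) {
  Nd <- cfg$n_detectors
  w1 <- cfg$blockA_widths[1]; w2 <- cfg$blockA_widths[2]
  wE <- cfg$aux_embedding_size
  L <- list(
    c1 = conv1d_layer(2L, w1, 3L), b1 = batchnorm_layer(w1), a1 = act_layer("elu"),
    c2 = conv1d_layer(w1, w1, 3L), b2 = batchnorm_layer(w1), a2 = act_layer("elu"),
    c3 = conv1d_layer(w1, w2, 3L), b3 = batchnorm_layer(w2), a3 = act_layer("lrelu"),
    c4 = conv1d_layer(w2, w2, kernel = Nd, stride = Nd, pad = 0L),
    b4 = batchnorm_layer(w2), a4 = act_layer("lrelu"),
    cE = conv1d_layer(w2, wE, kernel = 2L, stride = 2L, pad = 0L),
    bE = batchnorm_layer(wE), aE = act_layer("lrelu"),
    cBt = conv1d_layer(wE, wE, 3L), bBt = batchnorm_layer(wE), aBt = act_layer("lrelu"),
    gate = dense_layer(2L, wE), gsig = act_layer("sigmoid"),
    up = upsample1d(),
    cD = conv1d_layer(wE, w2, 3L), bD = batchnorm_layer(w2), aD = act_layer("lrelu"),
    c5 = conv1d_layer(w2, 16L, 3L))
  e <- new.env(parent = emptyenv())
  e$layers <- L
  e$forward <- function(x, aux, train = TRUE) {
    seq_fwd <- function(h, names) {
      for (nm in names) h <- L[[nm]]$forward(h, train)
      h
    }
    t0 <- seq_fwd(x, c("c1", "b1", "a1", "c2", "b2", "a2",
                       "c3", "b3", "a3", "c4", "b4", "a4"))   # (B, Ns, w2)
    bt <- seq_fwd(t0, c("cE", "bE", "aE", "cBt", "bBt", "aBt"))  # (B, Ns/2, wE)
    g <- 2 * L$gsig$forward(L$gate$forward(aux, train), train)   # (B, wE), mean ~1
    e$bt <- bt; e$g <- g
    gb <- bt
    for (l in seq_len(dim(bt)[2])) gb[, l, ] <- bt[, l, ] * g
    dec <- seq_fwd(gb, c("up", "cD", "bD", "aD"))
    h <- dec + t0                                               # skip connection
    out <- L$c5$forward(h, train)                               # (B, Ns, 16)
    d <- dim(out)
    dim(out) <- c(d[1], d[2] * d[3])                            # (B, 16*Ns)
    e$out_dim <- d
    out
  }
  e$backward <- function(dy) {
    dim(dy) <- e$out_dim
    dh <- L$c5$backward(dy)
    ddec <- dh          # gradient into decoder branch
    dt0_skip <- dh      # and into the skip
    dgb <- L$up$backward(L$cD$backward(L$bD$backward(L$aD$backward(ddec))))
    # gating backward
    bt <- e$bt; g <- e$g
    dbt <- dgb
    dgsum <- matrix(0, nrow(g), ncol(g))
    for (l in seq_len(dim(bt)[2])) {
      dbt[, l, ] <- dgb[, l, ] * g
      dgsum <- dgsum + dgb[, l, ] * bt[, l, ]
    }
    daux <- L$gate$backward(L$gsig$backward(dgsum) * 2)
    seq_bwd <- function(dh, names) {
      for (nm in rev(names)) dh <- L[[nm]]$backward(dh)
      dh
    }
    dt0 <- seq_bwd(dbt, c("cE", "bE", "aE", "cBt", "bBt", "aBt")) + dt0_skip
    dx <- seq_bwd(dt0, c("c1", "b1", "a1", "c2", "b2", "a2",
                         "c3", "b3", "a3", "c4", "b4", "a4"))
    list(dx = dx, daux = daux)
  }
  e
}

## ---- U-net (3 levels, additive usage handled by the caller) ----

make_unet <- function(in_ch, out_ch, widths) {
  w1 <- widths[1]; w2 <- widths[2]; w3 <- widths[3]
  L <- list(
    c11 = conv2d_layer(in_ch, w1), b11 = batchnorm_layer(w1), a11 = act_layer("lrelu"),
    c12 = conv2d_layer(w1, w1), b12 = batchnorm_layer(w1), a12 = act_layer("lrelu"),
    p1 = avgpool2d(),
    c21 = conv2d_layer(w1, w2), b21 = batchnorm_layer(w2), a21 = act_layer("lrelu"),
    c22 = conv2d_layer(w2, w2), b22 = batchnorm_layer(w2), a22 = act_layer("lrelu"),
    p2 = avgpool2d(),
    c31 = conv2d_layer(w2, w3), b31 = batchnorm_layer(w3), a31 = act_layer("lrelu"),
    c32 = conv2d_layer(w3, w3), b32 = batchnorm_layer(w3), a32 = act_layer("lrelu"),
    u2 = upsample2d(),
    cu2 = conv2d_layer(w3, w2), bu2 = batchnorm_layer(w2), au2 = act_layer("lrelu"),
    c23 = conv2d_layer(2L * w2, w2), b23 = batchnorm_layer(w2), a23 = act_layer("lrelu"),
    u1 = upsample2d(),
    cu1 = conv2d_layer(w2, w1), bu1 = batchnorm_layer(w1), au1 = act_layer("lrelu"),
    c13 = conv2d_layer(2L * w1, w1), b13 = batchnorm_layer(w1), a13 = act_layer("lrelu"),
    cf = conv2d_layer(w1, out_ch))
  e <- new.env(parent = emptyenv())
  e$layers <- L
  sf <- function(h, names, train) { for (nm in names) h <- L[[nm]]$forward(h, train); h }
  sb <- function(dh, names) { for (nm in rev(names)) dh <- L[[nm]]$backward(dh); dh }
  cat4 <- function(a, b) {
    d <- dim(a)
    out <- array(0, c(d[1], d[2], d[3], d[4] + dim(b)[4]))
    out[, , , seq_len(d[4])] <- a
    out[, , , d[4] + seq_len(dim(b)[4])] <- b
    out
  }
  e$forward <- function(x, train = TRUE) {
    e1 <- sf(x, c("c11", "b11", "a11", "c12", "b12", "a12"), train)
    e2 <- sf(L$p1$forward(e1, train), c("c21", "b21", "a21", "c22", "b22", "a22"), train)
    e3 <- sf(L$p2$forward(e2, train), c("c31", "b31", "a31", "c32", "b32", "a32"), train)
    u2 <- sf(L$u2$forward(e3, train), c("cu2", "bu2", "au2"), train)
    d2 <- sf(cat4(u2, e2), c("c23", "b23", "a23"), train)
    u1 <- sf(L$u1$forward(d2, train), c("cu1", "bu1", "au1"), train)
    d1 <- sf(cat4(u1, e1), c("c13", "b13", "a13"), train)
    e$w_split <- c(dim(u1)[4], dim(u2)[4])
    L$cf$forward(d1, train)
  }
  e$backward <- function(dy) {
    dd1 <- sb(L$cf$backward(dy), c("c13", "b13", "a13"))
    k1 <- e$w_split[1]
    du1 <- dd1[, , , seq_len(k1), drop = FALSE]
    de1_cat <- dd1[, , , k1 + seq_len(dim(dd1)[4] - k1), drop = FALSE]
    dd2 <- L$u1$backward(sb(du1, c("cu1", "bu1", "au1")))
    dd2 <- sb(dd2, c("c23", "b23", "a23"))
    k2 <- e$w_split[2]
    du2 <- dd2[, , , seq_len(k2), drop = FALSE]
    de2_cat <- dd2[, , , k2 + seq_len(dim(dd2)[4] - k2), drop = FALSE]
    de3 <- L$u2$backward(sb(du2, c("cu2", "bu2", "au2")))
    de2 <- sb(de3, c("c31", "b31", "a31", "c32", "b32", "a32"))
    de2 <- L$p2$backward(de2) + de2_cat
    de1 <- sb(de2, c("c21", "b21", "a21", "c22", "b22", "a22"))
    de1 <- L$p1$backward(de1) + de1_cat
    sb(de1, c("c11", "b11", "a11", "c12", "b12", "a12"))
  }
  e
}

## ---- full model ----

#' Assemble the sensor-to-image network
#'
#' Builds the full branching model: measurement tensor (flattened per
#' channel) and auxiliary scalars in, a contrast-image path (block A domain
#' transform, masked fully connected image former, residual U-net, sigmoid)
#' and a background path (block B, softplus) out. Weights use seeded
#' Glorot-uniform initialization.
#'
#' @param config a \code{dot_nn_config}.
#' @param seed optional integer seed for the weight initialization.
#' @return a \code{dot_nn_model} environment.
#' @export
assemble_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "dot_nn_config"))
  if (!is.null(seed)) set.seed(seed)
  g <- config$grid_size
  m <- new.env(parent = emptyenv())
  m$cfg <- config
  m$blockB <- make_blockB(config)
  m$blockA <- make_blockA(config)
  m$fc1 <- dense_layer(16L * config$n_sources, config$fc_hidden)
  m$afc <- act_layer("lrelu")
  m$fc2 <- dense_layer(config$fc_hidden, g * g * 2L)
  # start the contrast images near the data prior (mostly background, i.e.
  # contrast ~ 0.1) instead of sigmoid(0) = 0.5
  m$fc2$params$b[] <- -2
  m$sig <- act_layer("sigmoid")
  m$unets <- if (config$two_path) {
    list(make_unet(2L, 1L, config$unet_widths), make_unet(2L, 1L, config$unet_widths))
  } else {
    list(make_unet(2L, 2L, config$unet_widths))
  }
  m$mask <- image_grid(g, 1)$mask     # circular mask depends only on the grid
  m$mask_flat <- c(as.vector(m$mask), as.vector(m$mask))
  m$norm <- NULL                      # input normalization, set by the trainer
  class(m) <- "dot_nn_model"
  m
}

# every trainable layer of the model, flat list
nn_all_layers <- function(m) {
  c(m$blockB$layers, m$blockA$layers,
    list(fc1 = m$fc1, afc = m$afc, fc2 = m$fc2, sig = m$sig),
    do.call(c, lapply(m$unets, function(u) u$layers)))
}

#' @export
print.dot_nn_model <- function(x, ...) {
  np <- sum(vapply(nn_all_layers(x), function(l)
    sum(vapply(l$params, length, 1L)), 1L))
  cat(sprintf("<dot_nn_model> preset=%s, %d trainable parameters, %s\n",
              x$cfg$preset, np,
              if (is.null(x$norm)) "untrained" else "normalization set"))
  invisible(x)
}

# forward pass; X (B, Ns*Nd, 2) normalized, aux (B, 2) normalized
nn_forward <- function(m, X, aux, train = FALSE) {
  g <- m$cfg$grid_size
  bg <- m$blockB$forward(X, aux, train)
  feat <- m$blockA$forward(X, aux, train)
  h <- m$afc$forward(m$fc1$forward(feat, train), train)
  pre <- m$fc2$forward(h, train)
  pre <- pre * rep(m$mask_flat, each = nrow(pre))
  dim(pre) <- c(nrow(X), g, g, 2L)
  if (m$cfg$two_path) {
    delta <- array(0, dim(pre))
    delta[, , , 1] <- m$unets[[1]]$forward(pre, train)
    delta[, , , 2] <- m$unets[[2]]$forward(pre, train)
  } else {
    delta <- m$unets[[1]]$forward(pre, train)
  }
  z <- m$sig$forward(pre + delta, train)
  contrast <- mask_mul(z, m$mask)
  list(contrast = contrast, background = bg)
}

# backward pass for gradients dL/dcontrast and dL/dbackground
nn_backward <- function(m, dcontrast, dbackground) {
  g <- m$cfg$grid_size
  m$blockB$backward(dbackground)
  dz <- mask_mul(dcontrast, m$mask)
  dpre_sum <- m$sig$backward(dz)
  if (m$cfg$two_path) {
    dpre <- dpre_sum +
      m$unets[[1]]$backward(dpre_sum[, , , 1, drop = FALSE]) +
      m$unets[[2]]$backward(dpre_sum[, , , 2, drop = FALSE])
  } else {
    dpre <- dpre_sum + m$unets[[1]]$backward(dpre_sum)
  }
  B <- dim(dpre)[1]
  dim(dpre) <- c(B, g * g * 2L)
  dpre <- dpre * rep(m$mask_flat, each = B)
  dfeat <- m$fc1$backward(m$afc$backward(m$fc2$backward(dpre)))
  m$blockA$backward(dfeat)
  invisible(NULL)
}

#' Loss weights of the composite coefficient loss
#'
#' Defaults: contrast-image terms and the scattering background weighted 1,
#' the absorption background weighted 100^2 (absorption coefficients are
#' about 100x smaller than scattering, so this balances the contributions).
#'
#' @param w_ima,w_ims weights of the two contrast-image MSEs.
#' @param w_a weight of the background absorption MSE (default 100^2).
#' @param w_s weight of the background scattering MSE.
#' @return a \code{dot_loss_weights}.
#' @export
loss_weights <- function(w_ima = 1, w_ims = 1, w_a = 100^2, w_s = 1) {
  stopifnot(w_ima >= 0, w_ims >= 0, w_a >= 0, w_s >= 0)
  structure(list(w_ima = w_ima, w_ims = w_ims, w_a = w_a, w_s = w_s),
            class = "dot_loss_weights")
}

#' Composite reconstruction loss Q
#'
#' \code{Q = w_ima MSE(c_a) + w_ims MSE(c_s) + w_a MSE(mu_a0) + w_s MSE(mu_s0)},
#' where the image MSEs average over the pixels inside the circular mask
#' (and over the batch) and the background MSEs average over the batch.
#'
#' @param pred list with \code{contrast} (B x g x g x 2 array, or g x g x 2
#'   for a single sample) and \code{background} (B x 2).
#' @param truth same structure.
#' @param weights a \code{dot_loss_weights}.
#' @param mask logical g x g matrix of valid pixels (default: the inscribed
#'   circle).
#' @return scalar Q (nonnegative; 0 iff all four components match).
#' @export
loss_Q <- function(pred, truth, weights = loss_weights(), mask = NULL) {
  pc <- pred$contrast; tc <- truth$contrast
  if (length(dim(pc)) == 3) { dim(pc) <- c(1, dim(pc)); }
  if (length(dim(tc)) == 3) { dim(tc) <- c(1, dim(tc)); }
  pb <- rbind(pred$background); tb <- rbind(truth$background)
  if (!all(dim(pc) == dim(tc)) || !all(dim(pb) == dim(tb))) stop("shape mismatch")
  g <- dim(pc)[2]
  if (is.null(mask)) mask <- image_grid(g, 1)$mask
  B <- dim(pc)[1]
  midx <- which(mask)
  nm <- length(midx)
  msel <- function(x, ch) {   # (B, nm) matrix of masked pixels
    xc <- x[, , , ch, drop = FALSE]; dim(xc) <- c(B, g * g)
    xc[, midx, drop = FALSE]
  }
  mse_a <- mean((msel(pc, 1) - msel(tc, 1))^2)
  mse_s <- mean((msel(pc, 2) - msel(tc, 2))^2)
  weights$w_ima * mse_a + weights$w_ims * mse_s +
    weights$w_a * mean((pb[, 1] - tb[, 1])^2) +
    weights$w_s * mean((pb[, 2] - tb[, 2])^2)
}

# gradients of loss_Q w.r.t. prediction (batch form)
loss_Q_grad <- function(pred, truth, weights, mask) {
  pc <- pred$contrast; tc <- truth$contrast
  B <- dim(pc)[1]
  nm <- sum(mask)
  dc <- array(0, dim(pc))
  dc[, , , 1] <- 2 * weights$w_ima / (B * nm) * (pc[, , , 1] - tc[, , , 1])
  dc[, , , 2] <- 2 * weights$w_ims / (B * nm) * (pc[, , , 2] - tc[, , , 2])
  dc <- mask_mul(dc, mask)
  db <- cbind(2 * weights$w_a / B * (pred$background[, 1] - truth$background[, 1]),
              2 * weights$w_s / B * (pred$background[, 2] - truth$background[, 2]))
  list(dcontrast = dc, dbackground = db)
}
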