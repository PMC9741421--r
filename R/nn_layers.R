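# Minimal layer library with hand-written backpropagation.
#
# Tensors are plain R arrays: 1-D feature maps are (batch, length, channels),
# images are (batch, height, width, channels). Convolutions are realized as
# im2col gathers followed by one BLAS matrix multiply, which is where all the
# heavy lifting happens. Each layer is an environment exposing
#   $params / $grads : named lists of arrays (same shapes)
#   $forward(x, train) -> y      (caches what backward needs)
#   $backward(dy) -> dx          (writes $grads)
# One backward per forward; the trainer zeroes/consumes grads per batch.

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

new_layer <- function(params = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim(p)))
  e
}

## ---- activations (stateless, but kept as layers for uniform wiring) ----

act_layer <- function(kind, alpha = 0.2) {
  e <- new_layer()
  e$forward <- function(x, train = TRUE) {
    e$x <- x
    switch(kind,
      relu = pmax(x, 0),
      lrelu = pmax(x, 0) + alpha * pmin(x, 0),
      elu = pmax(x, 0) + expm1(pmin(x, 0)),
      sigmoid = 1 / (1 + exp(-x)),
      softplus = pmax(x, 0) + log1p(exp(-abs(x))))   # numerically stable
  }
  e$backward <- function(dy) {
    x <- e$x
    g <- switch(kind,
      relu = (x > 0) + 0,
      lrelu = alpha + (1 - alpha) * (x > 0),
      elu = { p <- (x > 0); p + exp(pmin(x, 0)) * (1 - p) },
      sigmoid = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
      softplus = 1 / (1 + exp(-x)))
    dy * g
  }
  e
}

## ---- dense ----

dense_layer <- function(n_in, n_out) {
  e <- new_layer(list(W = glorot(n_in, n_out, c(n_in, n_out)),
                      b = array(0, n_out)))
  e$forward <- function(x, train = TRUE) {   # x: (B, n_in)
    e$x <- x
    sweep(x %*% e$params$W, 2, e$params$b, `+`)
  }
  e$backward <- function(dy) {
    e$grads$W <- crossprod(e$x, dy)
    e$grads$b <- colSums(dy)
    dy %*% t(e$params$W)
  }
  e
}

## ---- 1-D convolution ----

conv1d_layer <- function(in_ch, out_ch, kernel, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- if (stride == 1L) (kernel - 1L) %/% 2L else 0L
  e <- new_layer(list(W = glorot(kernel * in_ch, out_ch, c(kernel * in_ch, out_ch)),
                      b = array(0, out_ch)))
  e$kernel <- kernel; e$stride <- stride; e$pad <- pad
  e$forward <- function(x, train = TRUE) {   # x: (B, L, C)
    B <- dim(x)[1]; L <- dim(x)[2]; C <- dim(x)[3]
    Lp <- L + 2L * pad
    Lo <- (Lp - kernel) %/% stride + 1L
    if (pad > 0) {
      xp <- array(0, c(B, Lp, C)); xp[, (pad + 1):(pad + L), ] <- x
    } else xp <- x
    dim(xp) <- c(B, Lp * C)
    # one gather: column (pos, tap, ch) of the patch matrix, pos fastest
    starts <- (seq_len(Lo) - 1L) * stride
    if (is.null(e$colidx) || !identical(e$in_shape, c(B, L, C))) {
      pos_tap <- outer(starts, seq_len(kernel), `+`)        # Lo x k
      e$colidx <- as.vector(outer(as.vector(pos_tap), (seq_len(C) - 1L) * Lp, `+`))
      e$in_shape <- c(B, L, C)
    }
    cols <- xp[, e$colidx, drop = FALSE]                    # (B, Lo*k*C)
    dim(cols) <- c(B * Lo, kernel * C)
    out <- cols %*% e$params$W
    out <- out + rep(e$params$b, each = nrow(out))
    dim(out) <- c(B, Lo, out_ch)
    e$cache <- list(cols = cols, B = B, L = L, C = C, Lo = Lo,
                    Lp = Lp, starts = starts)
    out
  }
  e$backward <- function(dy) {
    ca <- e$cache
    dm <- dy; dim(dm) <- c(ca$B * ca$Lo, out_ch)
    e$grads$W <- crossprod(ca$cols, dm)
    e$grads$b <- colSums(dm)
    dcols <- dm %*% t(e$params$W)
    dim(dcols) <- c(ca$B, ca$Lo, kernel, ca$C)
    dxp <- matrix(0, ca$B, ca$Lp * ca$C)
    choff <- (seq_len(ca$C) - 1L) * ca$Lp
    for (kk in seq_len(kernel)) {   # within one tap, positions are distinct
      tgt <- as.vector(outer(ca$starts + kk, choff, `+`))
      sl <- dcols[, , kk, ]; dim(sl) <- c(ca$B, ca$Lo * ca$C)
      dxp[, tgt] <- dxp[, tgt] + sl
    }
    dim(dxp) <- c(ca$B, ca$Lp, ca$C)
    if (pad > 0) dxp[, (pad + 1):(pad + ca$L), , drop = FALSE] else dxp
  }
  e
}

## ---- 2-D convolution (3x3, stride 1, same padding) ----

conv2d_layer <- function(in_ch, out_ch, kernel = 3L) {
  stopifnot(kernel %% 2L == 1L)
  pad <- (kernel - 1L) %/% 2L
  K2 <- kernel * kernel
  e <- new_layer(list(W = glorot(K2 * in_ch, out_ch, c(K2 * in_ch, out_ch)),
                      b = array(0, out_ch)))
  # im2col + BLAS, implemented in C++ (src/conv.cpp); the patch matrix is
  # kept on the C++ side between forward and backward. conv2d_ref below is
  # the pure-R reference the tests check the kernels against.
  e$forward <- function(x, train = TRUE) {   # x: (B, H, W, C)
    r <- .conv2d_fwd_cpp(x, dim(x), e$params$W, e$params$b, kernel, pad, train)
    if (train) e$cache <- list(cols = r$cols, dims = dim(x))
    r$out
  }
  e$backward <- function(dy) {
    r <- .conv2d_bwd_cpp(e$cache$cols, e$cache$dims, e$params$W, dy, kernel, pad)
    e$cache <- NULL
    e$grads$W <- r$dW
    e$grads$b <- as.numeric(r$db)
    r$dx
  }
  e
}

# pure-R reference of the same convolution (shifted-slice GEMM per kernel
# tap); used as the independent oracle for the compiled kernels
conv2d_ref <- function(x, W, b, kernel = 3L) {
  pad <- (kernel - 1L) %/% 2L
  K2 <- kernel * kernel
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  out_ch <- ncol(W)
  xp <- array(0, c(B, H + 2 * pad, Wd + 2 * pad, C))
  xp[, (pad + 1):(pad + H), (pad + 1):(pad + Wd), ] <- x
  n <- B * H * Wd
  out <- matrix(rep(b, each = n), n, out_ch)
  t <- 0L
  for (dx in 0:(kernel - 1)) for (dyy in 0:(kernel - 1)) {
    t <- t + 1L
    sl <- xp[, (1 + dyy):(H + dyy), (1 + dx):(Wd + dx), , drop = FALSE]
    dim(sl) <- c(n, C)
    out <- out + sl %*% W[t + (seq_len(C) - 1L) * K2, , drop = FALSE]
  }
  dim(out) <- c(B, H, Wd, out_ch)
  out
}

## ---- batch normalization (channels-last, any spatial rank) ----

batchnorm_layer <- function(n_ch, momentum = 0.9, eps = 1e-5) {
  e <- new_layer(list(gamma = array(1, n_ch), beta = array(0, n_ch)))
  e$running_mean <- array(0, n_ch)
  e$running_var <- array(1, n_ch)
  flat <- function(x) { d <- dim(x); dim(x) <- c(prod(d[-length(d)]), d[length(d)]); x }
  e$forward <- function(x, train = TRUE) {
    d <- dim(x)
    xm <- flat(x)
    n <- nrow(xm)
    if (train) {
      mu <- colMeans(xm)
      v <- colMeans(xm * xm) - mu^2
      v[v < 0] <- 0
      e$running_mean <- momentum * e$running_mean + (1 - momentum) * mu
      e$running_var <- momentum * e$running_var + (1 - momentum) * v
    } else {
      mu <- e$running_mean; v <- e$running_var
    }
    istd <- 1 / sqrt(v + eps)
    scale <- e$params$gamma * istd
    out <- .scale_shift_cpp(xm, ncol(xm), scale, e$params$beta - mu * scale)
    dim(out) <- d
    e$cache <- list(xm = xm, mu = mu, istd = istd, d = d, train = train)
    out
  }
  e$backward <- function(dy) {
    ca <- e$cache
    dym <- flat(dy)
    n <- nrow(dym)
    C <- ncol(dym)
    xn <- .scale_shift_cpp(ca$xm, C, ca$istd, -ca$mu * ca$istd)
    dim(xn) <- dim(dym)
    e$grads$gamma <- colSums(dym * xn)
    e$grads$beta <- colSums(dym)
    if (ca$train) {
      # standard batch-norm backward through batch statistics:
      # dx = gamma*istd * (dxn - mean(dxn) - xn * mean(dxn * xn))
      dx <- dym - rep(colMeans(dym), each = n) -
        xn * rep(colMeans(dym * xn), each = n)
      dx <- .scale_shift_cpp(dx, C, e$params$gamma * ca$istd, numeric(C))
    } else {
      dx <- .scale_shift_cpp(dym, C, e$params$gamma * ca$istd, numeric(C))
    }
    dim(dx) <- ca$d
    dx
  }
  e
}

## ---- pooling / resampling ----

global_avg_pool1d <- function() {
  e <- new_layer()
  e$forward <- function(x, train = TRUE) {   # (B, L, C) -> (B, C)
    e$d <- dim(x)
    apply(x, c(1, 3), mean)
  }
  e$backward <- function(dy) {
    d <- e$d
    dx <- array(0, d)
    for (l in seq_len(d[2])) dx[, l, ] <- dy / d[2]
    dx
  }
  e
}

avgpool2d <- function() {
  e <- new_layer()
  e$forward <- function(x, train = TRUE) {   # 2x2 mean, stride 2
    d <- dim(x); e$d <- d
    H2 <- d[2] %/% 2L; W2 <- d[3] %/% 2L
    o1 <- seq(1, d[2], 2); o2 <- seq(2, d[2], 2)
    p1 <- seq(1, d[3], 2); p2 <- seq(2, d[3], 2)
    0.25 * (x[, o1, p1, , drop = FALSE] + x[, o2, p1, , drop = FALSE] +
              x[, o1, p2, , drop = FALSE] + x[, o2, p2, , drop = FALSE])
  }
  e$backward <- function(dy) {
    d <- e$d
    dx <- array(0, d)
    o1 <- seq(1, d[2], 2); o2 <- seq(2, d[2], 2)
    p1 <- seq(1, d[3], 2); p2 <- seq(2, d[3], 2)
    q <- 0.25 * dy
    dx[, o1, p1, ] <- q; dx[, o2, p1, ] <- q
    dx[, o1, p2, ] <- q; dx[, o2, p2, ] <- q
    dx
  }
  e
}

upsample2d <- function() {
  e <- new_layer()
  e$forward <- function(x, train = TRUE) {   # nearest-neighbor x2
    d <- dim(x); e$d <- d
    x[, rep(seq_len(d[2]), each = 2), rep(seq_len(d[3]), each = 2), , drop = FALSE]
  }
  e$backward <- function(dy) {
    d <- e$d
    o1 <- seq(1, 2 * d[2], 2); o2 <- seq(2, 2 * d[2], 2)
    p1 <- seq(1, 2 * d[3], 2); p2 <- seq(2, 2 * d[3], 2)
    dy[, o1, p1, , drop = FALSE] + dy[, o2, p1, , drop = FALSE] +
      dy[, o1, p2, , drop = FALSE] + dy[, o2, p2, , drop = FALSE]
  }
  e
}

upsample1d <- function() {
  e <- new_layer()
  e$forward <- function(x, train = TRUE) {
    d <- dim(x); e$d <- d
    x[, rep(seq_len(d[2]), each = 2), , drop = FALSE]
  }
  e$backward <- function(dy) {
    d <- e$d
    dy[, seq(1, 2 * d[2], 2), , drop = FALSE] +
      dy[, seq(2, 2 * d[2], 2), , drop = FALSE]
  }
  e
}

## ---- Adam optimizer over a list of layers ----

adam_state <- function(layers) {
  lapply(layers, function(l) lapply(l$params, function(p)
    list(m = array(0, dim(p)), v = array(0, dim(p)))))
}

adam_update <- function(layers, state, lr, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8, t = 1) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (!length(l$params)) next
    for (pn in names(l$params)) {
      g <- l$grads[[pn]]
      st <- state[[li]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[li]][[pn]] <- st
      l$params[[pn]] <- l$params[[pn]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  state
}

# deep copy / restore of all trainable and running state (for best-epoch
# selection and model serialization)
snapshot_layers <- function(layers) {
  lapply(layers, function(l) {
    s <- list(params = l$params)
    if (!is.null(l$running_mean)) {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

restore_layers <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running_mean)) {
      layers[[i]]$running_mean <- snap[[i]]$running_mean
      layers[[i]]$running_var <- snap[[i]]$running_var
    }
  }
  invisible(layers)
}
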