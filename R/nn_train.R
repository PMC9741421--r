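#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with beta1 = 0.5,
#' learning rate 0.0002, batch size 32, 200 epochs. The tested weights are
#' taken from the epoch with the lowest validation loss (automating the
#' manual early-epoch selection used to sidestep overfitting).
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size minibatch size.
#' @param epochs number of epochs.
#' @param seed integer seed for shuffling and weight initialization.
#' @param selection "best_validation" or "last".
#' @return a \code{dot_training_config}.
#' @export
training_config <- function(learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                            batch_size = 32L, epochs = 200L, seed = 1L,
                            selection = c("best_validation", "last")) {
  selection <- match.arg(selection)
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), selection = selection),
            class = "dot_training_config")
}

# dataset inputs (N, Ns, Nd, 2) -> sequence tensor (N, Ns*Nd, 2) with the
# detector index fastest within each source block
flatten_inputs <- function(inputs) {
  d <- dim(inputs)
  out <- array(0, c(d[1], d[2] * d[3], 2))
  out[, , 1] <- aperm(inputs[, , , 1, drop = FALSE], c(1, 3, 2, 4))
  out[, , 2] <- aperm(inputs[, , , 2, drop = FALSE], c(1, 3, 2, 4))
  out
}

# per-feature standardization statistics from the training split
fit_normalization <- function(X, aux, cfg) {
  mu <- apply(X, c(2, 3), mean)
  sd <- apply(X, c(2, 3), stats::sd)
  sd[sd < 1e-12] <- 1
  list(input_mean = mu, input_sd = sd, aux_ranges = cfg$aux_ranges)
}

apply_normalization <- function(norm, X, aux) {
  B <- dim(X)[1]; L <- dim(X)[2]
  for (ch in 1:2) {
    xm <- matrix(X[, , ch], B, L)
    X[, , ch] <- sweep(sweep(xm, 2, norm$input_mean[, ch]),
                       2, norm$input_sd[, ch], `/`)
  }
  r <- norm$aux_ranges
  aux <- cbind((aux[, 1] - r[1, 1]) / (r[1, 2] - r[1, 1]),
               (aux[, 2] - r[2, 1]) / (r[2, 2] - r[2, 1]))
  list(X = X, aux = aux)
}

# batched evaluation of the Q loss over a set of indices (eval mode)
evaluate_Q <- function(model, X, aux, truth_contrast, truth_background,
                       idx, weights, chunk = 64L) {
  total <- 0
  for (start in seq(1, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1, length(idx))]
    pred <- nn_forward(model, X[sel, , , drop = FALSE], aux[sel, , drop = FALSE],
                       train = FALSE)
    q <- loss_Q(pred,
                list(contrast = truth_contrast[sel, , , , drop = FALSE],
                     background = truth_background[sel, , drop = FALSE]),
                weights, model$mask)
    total <- total + q * length(sel)
  }
  total / length(idx)
}

#' Train the sensor-to-image network
#'
#' Minimizes the composite Q loss with Adam over the training split of a
#' generated dataset, evaluating the validation Q after each epoch. Input
#' features are standardized with training-split statistics (stored in the
#' model); auxiliary scalars are min-max scaled by their design ranges. The
#' returned model carries the weights of the selected epoch.
#'
#' @param model a \code{dot_nn_model} from \code{\link{assemble_network}}.
#' @param dataset a \code{dot_dataset}.
#' @param config a \code{dot_training_config}.
#' @param weights a \code{dot_loss_weights}.
#' @param verbose print per-epoch losses.
#' @return a \code{dot_trained_model}: list with the \code{model}, a
#'   \code{history} data frame (epoch, train_Q, validation_Q), the
#'   \code{selected_epoch} and the config.
#' @export
train_network <- function(model, dataset, config = training_config(),
                          weights = loss_weights(), verbose = FALSE) {
  stopifnot(inherits(model, "dot_nn_model"), inherits(dataset, "dot_dataset"))
  set.seed(config$seed)
  Xall <- flatten_inputs(dataset$inputs)
  train_idx <- which(dataset$split == "train")
  val_idx <- which(dataset$split == "validation")
  if (!length(train_idx) || !length(val_idx)) stop("dataset split missing")

  model$norm <- fit_normalization(Xall[train_idx, , , drop = FALSE],
                                  dataset$aux[train_idx, , drop = FALSE], model$cfg)
  nx <- apply_normalization(model$norm, Xall, dataset$aux)
  X <- nx$X; aux <- nx$aux
  tc <- dataset$truth_contrast
  tb <- dataset$truth_background

  layers <- nn_all_layers(model)
  opt <- adam_state(layers)
  history <- data.frame(epoch = integer(0), train_Q = numeric(0),
                        validation_Q = numeric(0))
  best_val <- Inf; best_snap <- NULL; best_epoch <- NA_integer_
  t_step <- 0L

  for (ep in seq_len(config$epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0; nb <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1, length(ord))]
      pred <- nn_forward(model, X[sel, , , drop = FALSE],
                         aux[sel, , drop = FALSE], train = TRUE)
      truth <- list(contrast = tc[sel, , , , drop = FALSE],
                    background = tb[sel, , drop = FALSE])
      q <- loss_Q(pred, truth, weights, model$mask)
      if (!is.finite(q)) stop(sprintf("non-finite loss at epoch %d", ep))
      gr <- loss_Q_grad(pred, truth, weights, model$mask)
      nn_backward(model, gr$dcontrast, gr$dbackground)
      t_step <- t_step + 1L
      opt <- adam_update(layers, opt, config$learning_rate,
                         config$beta1, config$beta2, t = t_step)
      ep_loss <- ep_loss + q; nb <- nb + 1
    }
    val_Q <- evaluate_Q(model, X, aux, tc, tb, val_idx, weights)
    history <- rbind(history, data.frame(epoch = ep, train_Q = ep_loss / nb,
                                         validation_Q = val_Q))
    if (val_Q < best_val) {
      best_val <- val_Q
      best_snap <- snapshot_layers(layers)
      best_epoch <- ep
    }
    if (verbose) {
      message(sprintf("epoch %3d  train Q %.5g  val Q %.5g", ep, ep_loss / nb, val_Q))
    }
  }
  if (config$selection == "best_validation" && !is.null(best_snap)) {
    restore_layers(layers, best_snap)
  } else {
    best_epoch <- config$epochs
  }
  structure(list(model = model, history = history,
                 selected_epoch = best_epoch, config = config,
                 weights = weights),
            class = "dot_trained_model")
}

#' @export
print.dot_trained_model <- function(x, ...) {
  cat(sprintf("<dot_trained_model> %d epoch(s), selected epoch %d (val Q %.5g)\n",
              nrow(x$history), x$selected_epoch,
              x$history$validation_Q[x$selected_epoch]))
  invisible(x)
}

#' Reconstruct coefficient images from a measurement set
#'
#' Runs the trained network on one measurement set and denormalizes:
#' absolute coefficient = (contrast * (c_max - 1) + 1) x predicted
#' background, zero outside the circular mask.
#'
#' @param trained a \code{dot_trained_model} (or a \code{dot_nn_model} with
#'   normalization set).
#' @param meas a \code{dot_measurement} with the probe shape the model was
#'   built for.
#' @return a \code{dot_image} with absolute coefficient grids and the
#'   predicted backgrounds in \code{mu_a0}, \code{mu_s0}.
#' @export
reconstruct_nn <- function(trained, meas) {
  model <- if (inherits(trained, "dot_trained_model")) trained$model else trained
  if (is.null(model$norm)) stop("model has no normalization statistics; train it first")
  cfg <- model$cfg
  if (!all(dim(meas$log_amplitude) == c(cfg$n_sources, cfg$n_detectors))) {
    stop("measurement shape does not match the network configuration")
  }
  inputs <- array(0, c(1, cfg$n_sources, cfg$n_detectors, 2))
  inputs[1, , , 1] <- meas$log_amplitude
  inputs[1, , , 2] <- meas$phase_lag
  X <- flatten_inputs(inputs)
  aux <- matrix(c(meas$frequency_MHz, meas$diameter_mm), 1, 2)
  nx <- apply_normalization(model$norm, X, aux)
  pred <- nn_forward(model, nx$X, nx$aux, train = FALSE)
  bg <- pred$background[1, ]
  con <- pred$contrast[1, , , ]
  ma <- (con[, , 1] * (cfg$c_max - 1) + 1) * bg[1]
  ms <- (con[, , 2] * (cfg$c_max - 1) + 1) * bg[2]
  ma[!model$mask] <- 0
  ms[!model$mask] <- 0
  structure(list(mu_a_grid = ma, mu_s_grid = ms, mask = model$mask,
                 kind = "absolute", diameter_mm = meas$diameter_mm,
                 mu_a0 = bg[1], mu_s0 = bg[2]),
            class = "dot_image")
}

#' Save / load a trained model
#'
#' Serializes weights, running statistics, normalization and configuration
#' to RDS with a JSON configuration sidecar.
#'
#' @param trained a \code{dot_trained_model}.
#' @param path output .rds path.
#' @return invisibly, \code{path}; \code{load_model} returns the restored
#'   \code{dot_trained_model}.
#' @export
save_model <- function(trained, path) {
  stopifnot(inherits(trained, "dot_trained_model"))
  blob <- list(cfg = unclass(trained$model$cfg),
               norm = trained$model$norm,
               snapshot = snapshot_layers(nn_all_layers(trained$model)),
               history = trained$history,
               selected_epoch = trained$selected_epoch,
               config = unclass(trained$config),
               weights = unclass(trained$weights))
  saveRDS(blob, path, version = 2)
  cfg_json <- trained$model$cfg
  cfg_json$aux_ranges <- as.data.frame(cfg_json$aux_ranges)
  jsonlite::write_json(unclass(cfg_json), paste0(sub("\\.rds$", "", path), "_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  cfg <- do.call(network_config, blob$cfg[c("n_sources", "n_detectors", "grid_size",
                                            "preset", "blockB_channels", "blockA_widths",
                                            "aux_embedding_size", "fc_hidden", "fcB_hidden",
                                            "unet_widths", "two_path", "c_max", "bg_scale")])
  cfg$aux_ranges <- blob$cfg$aux_ranges
  model <- assemble_network(cfg)
  restore_layers(nn_all_layers(model), blob$snapshot)
  model$norm <- blob$norm
  structure(list(model = model, history = blob$history,
                 selected_epoch = blob$selected_epoch,
                 config = do.call(training_config, blob$config),
                 weights = do.call(loss_weights, blob$weights)),
            class = "dot_trained_model")
}
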