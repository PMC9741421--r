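#' Interpolate a nodal field onto the image grid
#'
#' Barycentric-linear interpolation of a per-node field at the pixel centers
#' of the \code{grid_size} x \code{grid_size} grid spanning the mesh disk.
#' Pixels whose center lies outside the inscribed circle are 0. Pixels inside
#' the mask but outside every element (a thin sliver between the polygonal
#' outer ring and the true circle) fall back to the nearest element.
#'
#' @param nodal_values numeric vector, one value per mesh node.
#' @param mesh a \code{dot_mesh}.
#' @param grid_size pixels per side (default 64).
#' @return grid_size x grid_size matrix (row = y index from minimum y).
#' @export
interpolate_to_grid <- function(nodal_values, mesh, grid_size = 64L) {
  if (length(nodal_values) != nrow(mesh$node_coords)) {
    stop("nodal_values length does not match mesh node count")
  }
  g <- image_grid(grid_size, mesh$diameter_mm)
  idx <- which(g$mask, arr.ind = TRUE)           # row = y, col = x
  pts <- cbind(g$x[idx[, 2]], g$y[idx[, 1]])
  loc <- locate_points(mesh, pts)
  vals <- numeric(nrow(pts))
  el <- mesh$elements
  e <- loc$element
  vals <- loc$bary[, 1] * nodal_values[el[e, 1]] +
    loc$bary[, 2] * nodal_values[el[e, 2]] +
    loc$bary[, 3] * nodal_values[el[e, 3]]
  out <- matrix(0, grid_size, grid_size)
  out[idx] <- vals
  out
}

#' Measurement noise model
#'
#' Multiplicative Gaussian amplitude noise (percent sigma, applied in linear
#' amplitude and re-logged) plus additive Gaussian phase noise in degrees.
#' Defaults emulate typical frequency-domain instrument noise: 1% amplitude,
#' 0.5 degree phase.
#'
#' @param amplitude_sigma_percent amplitude sigma in percent (>= 0).
#' @param phase_sigma_deg phase sigma in degrees (>= 0).
#' @return a \code{dot_noise} model.
#' @export
noise_model <- function(amplitude_sigma_percent = 1, phase_sigma_deg = 0.5) {
  stopifnot(amplitude_sigma_percent >= 0, phase_sigma_deg >= 0)
  structure(list(amplitude_sigma_percent = amplitude_sigma_percent,
                 phase_sigma_deg = phase_sigma_deg),
            class = "dot_noise")
}

#' Perturb a measurement set with instrument-like noise
#'
#' @param meas a \code{dot_measurement}.
#' @param noise a \code{dot_noise} model.
#' @return a noisy \code{dot_measurement}. Consumes the R random stream.
#' @export
add_measurement_noise <- function(meas, noise) {
  n <- length(meas$log_amplitude)
  amp_fac <- 1 + stats::rnorm(n, 0, noise$amplitude_sigma_percent / 100)
  amp_fac <- pmax(amp_fac, 1e-6)   # guard against nonpositive amplitude draws
  la <- meas$log_amplitude + log(amp_fac)
  ph <- (meas$phase_lag + stats::rnorm(n, 0, noise$phase_sigma_deg * pi / 180)) %% (2 * pi)
  measurement_set(matrix(la, nrow(meas$log_amplitude)),
                  matrix(ph, nrow(meas$phase_lag)),
                  meas$frequency_MHz, meas$diameter_mm)
}

#' Generate a training/validation dataset
#'
#' For each sample: draw a phantom (stratified exact inclusion-count
#' allocation), map it to the mesh, run the frequency-domain forward solver,
#' read the ring probe, add noise, and rasterize the contrast-image truth.
#' The split is 80/20 (exact counts), assigned by a seeded shuffle.
#'
#' @param n_samples number of samples.
#' @param ranges parameter ranges (\code{\link{default_ranges}}).
#' @param partition inclusion-count weights (\code{\link{default_partition}}).
#' @param noise a \code{dot_noise} (NULL for noiseless data).
#' @param seed integer seed controlling every random choice.
#' @param n_rings mesh refinement (32 reproduces the 3169-node mesh).
#' @param probe a \code{dot_probe}.
#' @param grid_size truth image resolution (default 64).
#' @param train_fraction training share of the split (default 0.8).
#' @param c_max maximum contrast for truth normalization (default 8).
#' @param progress print a line every 100 samples.
#' @return a \code{dot_dataset}: list with
#'   \code{inputs} (n x N_s x N_d x 2 array, log amplitude then phase lag),
#'   \code{aux} (n x 2: frequency MHz, diameter mm),
#'   \code{truth_contrast} (n x grid x grid x 2, normalized to [0, 1]),
#'   \code{truth_background} (n x 2: mu_a0, mu_s0),
#'   \code{split} (factor train/validation), \code{phantoms}, \code{mask},
#'   and the generation parameters.
#' @export
generate_dataset <- function(n_samples, ranges = default_ranges(),
                             partition = default_partition(),
                             noise = noise_model(), seed = 1L,
                             n_rings = 32L, probe = probe_geometry(),
                             grid_size = 64L, train_fraction = 0.8,
                             c_max = 8, progress = FALSE) {
  stopifnot(n_samples >= 1)
  set.seed(seed)
  counts <- allocate_inclusion_counts(n_samples, partition)
  counts <- sample(counts)                       # shuffle stratified labels
  Ns <- probe$n_sources; Nd <- probe$n_detectors

  inputs <- array(0, c(n_samples, Ns, Nd, 2))
  aux <- matrix(0, n_samples, 2,
                dimnames = list(NULL, c("frequency_MHz", "diameter_mm")))
  truth_contrast <- array(0, c(n_samples, grid_size, grid_size, 2))
  truth_background <- matrix(0, n_samples, 2,
                             dimnames = list(NULL, c("mu_a0", "mu_s0")))
  phantoms <- vector("list", n_samples)

  mesh_cache <- new.env()
  for (i in seq_len(n_samples)) {
    ph <- NULL
    for (attempt in 1:5) {
      ph_try <- sample_phantom(ranges, partition, n_inclusions = counts[i])
      key <- sprintf("%.9g", ph_try$diameter_mm)
      if (is.null(mesh_cache[[key]])) {
        mesh_cache[[key]] <- build_disk_mesh(n_rings, ph_try$diameter_mm)
      }
      m <- tryCatch(forward_measure(ph_try, mesh_cache[[key]], probe),
                    error = function(e) NULL)
      if (!is.null(m)) { ph <- ph_try; break }
    }
    if (is.null(ph)) stop(sprintf("forward solve failed repeatedly at sample %d", i))
    if (!is.null(noise)) m <- add_measurement_noise(m, noise)
    inputs[i, , , 1] <- m$log_amplitude
    inputs[i, , , 2] <- m$phase_lag
    aux[i, ] <- c(ph$frequency_MHz, ph$diameter_mm)
    tr <- rasterize_truth(ph, grid_size, kind = "contrast", c_max = c_max)
    truth_contrast[i, , , 1] <- tr$mu_a_grid
    truth_contrast[i, , , 2] <- tr$mu_s_grid
    truth_background[i, ] <- c(ph$mu_a0, ph$mu_s0)
    phantoms[[i]] <- ph
    if (progress && i %% 100 == 0) message(sprintf("  generated %d / %d", i, n_samples))
  }

  n_train <- round(train_fraction * n_samples)
  split <- rep("validation", n_samples)
  split[sample.int(n_samples, n_train)] <- "train"

  structure(list(
    inputs = inputs, aux = aux,
    truth_contrast = truth_contrast, truth_background = truth_background,
    split = factor(split, levels = c("train", "validation")),
    phantoms = phantoms,
    mask = image_grid(grid_size, 1)$mask,   # mask depends only on the grid
    params = list(n_samples = n_samples, seed = seed, n_rings = n_rings,
                  grid_size = grid_size, c_max = c_max,
                  train_fraction = train_fraction,
                  ranges = ranges, partition = as.numeric(partition),
                  noise = if (is.null(noise)) NULL else unclass(noise))
  ), class = "dot_dataset")
}

#' @export
print.dot_dataset <- function(x, ...) {
  cat(sprintf("<dot_dataset> %d samples (%d train / %d validation), probe %dx%d, grid %d\n",
              dim(x$inputs)[1], sum(x$split == "train"), sum(x$split == "validation"),
              dim(x$inputs)[2], dim(x$inputs)[3], dim(x$truth_contrast)[2]))
  invisible(x)
}

#' Save / load a dataset container
#'
#' Serializes the dataset to RDS with a human-readable JSON sidecar of
#' generation parameters and a phantom-parameter CSV (HDF5 bindings are not
#' assumed to be available).
#'
#' @param dataset a \code{dot_dataset}.
#' @param path output .rds path (sidecars use the same stem).
#' @return invisibly, \code{path}.
#' @export
save_dataset <- function(dataset, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  saveRDS(dataset, path, version = 2)
  stem <- sub("\\.rds$", "", path)
  jsonlite::write_json(dataset$params, paste0(stem, "_params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  export_phantoms(dataset$phantoms, paste0(stem, "_phantoms.csv"))
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "dot_dataset"))
  ds
}

#' Calibrate experimental measurements against a homogeneous reference
#'
#' Standard homogeneous-reference scheme: per-channel instrument gains are
#' removed by differencing the inhomogeneous and homogeneous measurements of
#' the same physical phantom (additive in the log-amplitude / phase domain)
#' and re-anchoring to a simulated homogeneous reference:
#' \code{calibrated = (inhomog - homog) + reference}.
#'
#' @param meas_inhomog experimental inhomogeneous \code{dot_measurement}.
#' @param meas_homog experimental homogeneous \code{dot_measurement}.
#' @param reference_homog simulated homogeneous reference.
#' @return calibrated \code{dot_measurement} on the simulation scale.
#' @export
calibrate_experimental <- function(meas_inhomog, meas_homog, reference_homog) {
  d <- dim(meas_inhomog$log_amplitude)
  if (!all(d == dim(meas_homog$log_amplitude)) ||
      !all(d == dim(reference_homog$log_amplitude))) {
    stop("measurement sets must share probe geometry")
  }
  la <- meas_inhomog$log_amplitude - meas_homog$log_amplitude +
    reference_homog$log_amplitude
  ph <- (meas_inhomog$phase_lag - meas_homog$phase_lag +
           reference_homog$phase_lag) %% (2 * pi)
  measurement_set(la, ph, reference_homog$frequency_MHz,
                  reference_homog$diameter_mm)
}
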