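# shared fixtures: everything is generated in code, no stored data

homogeneous_coeffs <- function(mesh, mu_a = 0.01, mu_s = 1.0) {
  structure(list(mu_a = rep(mu_a, nrow(mesh$node_coords)),
                 mu_s = rep(mu_s, nrow(mesh$node_coords))),
            class = "dot_coeffs")
}

single_inclusion_phantom <- function(d = 80, f = 50, mu_a0 = 0.01, mu_s0 = 1.0,
                                     r = d / 6, roc = d / 5, th = 45,
                                     c_a = 4, c_s = 2) {
  phantom(d, f, mu_a0, mu_s0,
          list(inclusion(r, roc, th, c_a, c_s)), margin = 0.95)
}

# weighted centroid of the top-decile perturbation of a nodal field
top_decile_centroid <- function(values, coords, background) {
  dmu <- values - background
  thr <- stats::quantile(dmu, 0.9)
  sel <- dmu >= thr
  colSums(coords[sel, , drop = FALSE] * dmu[sel]) / sum(dmu[sel])
}

# same for an image on the 64x64 grid
image_top_decile_centroid <- function(img_grid, mask, diameter_mm) {
  g <- image_grid(nrow(img_grid), diameter_mm)
  Xc <- matrix(g$x, nrow(img_grid), ncol(img_grid), byrow = TRUE)
  Yc <- matrix(g$y, nrow(img_grid), ncol(img_grid))
  v <- img_grid[mask]
  thr <- stats::quantile(v, 0.9)
  sel <- mask & img_grid >= thr
  w <- img_grid[sel]
  c(sum(Xc[sel] * w), sum(Yc[sel] * w)) / sum(w)
}

# tiny network configuration for architecture/gradient tests
tiny_config <- function(n_sources = 8L) {
  network_config(n_sources = n_sources, preset = "scaled",
                 blockB_channels = 4L, blockA_widths = c(4L, 6L),
                 aux_embedding_size = 8L, fc_hidden = 24L,
                 unet_widths = c(3L, 4L, 5L))
}

# stack a measurement set the way the inverse solver does
stack_meas <- function(m) c(as.vector(m$log_amplitude), as.vector(m$phase_lag))
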