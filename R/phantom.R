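#' Circular inclusion inside a phantom
#'
#' @param radius_mm inclusion radius (mm).
#' @param off_center_mm distance of the inclusion center from the phantom
#'   center (mm).
#' @param angle_deg angular position of the inclusion center in [0, 360).
#' @param contrast_a absorption contrast (inclusion / background), >= 1.
#' @param contrast_s reduced-scattering contrast, >= 1.
#' @return an object of class \code{dot_inclusion}.
#' @export
inclusion <- function(radius_mm, off_center_mm, angle_deg, contrast_a, contrast_s) {
  stopifnot(radius_mm > 0, off_center_mm >= 0, contrast_a >= 1, contrast_s >= 1)
  structure(list(radius_mm = radius_mm, off_center_mm = off_center_mm,
                 angle_deg = angle_deg %% 360,
                 contrast_a = contrast_a, contrast_s = contrast_s),
            class = "dot_inclusion")
}

#' Circular breast-like phantom description
#'
#' A homogeneous circular background of diameter \code{diameter_mm} holding
#' 0-2 circular inclusions with multiplicative optical contrast. Inclusions
#' must lie fully inside the phantom (with the containment margin used by the
#' sampler, \code{off_center + radius <= margin * diameter/2}).
#'
#' @param diameter_mm phantom diameter (mm).
#' @param frequency_MHz source modulation frequency (MHz).
#' @param mu_a0 background absorption coefficient (1/mm).
#' @param mu_s0 background reduced scattering coefficient (1/mm).
#' @param inclusions list of \code{dot_inclusion} (length 0-2).
#' @param margin containment margin as a fraction of the radius (default 1,
#'   i.e. only require the inclusion inside the disk; the sampler uses 0.95).
#' @return an object of class \code{dot_phantom}.
#' @export
phantom <- function(diameter_mm, frequency_MHz, mu_a0, mu_s0,
                    inclusions = list(), margin = 1) {
  stopifnot(diameter_mm > 0, frequency_MHz >= 0, mu_a0 > 0, mu_s0 > 0,
            length(inclusions) <= 2)
  R <- diameter_mm / 2
  for (inc in inclusions) {
    stopifnot(inherits(inc, "dot_inclusion"))
    if (inc$off_center_mm + inc$radius_mm > margin * R + 1e-9) {
      stop(sprintf("inclusion (r=%.3g, r_oc=%.3g) not contained in phantom of radius %.3g",
                   inc$radius_mm, inc$off_center_mm, R))
    }
  }
  structure(list(diameter_mm = diameter_mm, frequency_MHz = frequency_MHz,
                 mu_a0 = mu_a0, mu_s0 = mu_s0, inclusions = inclusions),
            class = "dot_phantom")
}

#' @export
print.dot_phantom <- function(x, ...) {
  cat(sprintf("<dot_phantom> D=%.4g mm, f=%.4g MHz, mu_a0=%.4g, mu_s0=%.4g, %d inclusion(s)\n",
              x$diameter_mm, x$frequency_MHz, x$mu_a0, x$mu_s0, length(x$inclusions)))
  invisible(x)
}

#' Default phantom parameter ranges
#'
#' The breast-like training ranges: diameter 60-150 mm, modulation frequency
#' 10-100 MHz, background absorption 0.005-0.03 /mm, background reduced
#' scattering 0.5-3 /mm, inclusion radius 4-17 mm, inclusion-to-background
#' contrast 1.5-8 (independently for absorption and scattering).
#'
#' @return a named list of c(min, max) ranges.
#' @export
default_ranges <- function() {
  list(diameter_mm = c(60, 150), frequency_MHz = c(10, 100),
       mu_a0 = c(0.005, 0.03), mu_s0 = c(0.5, 3),
       radius_mm = c(4, 17), contrast = c(1.5, 8))
}

#' Default inclusion-count partition
#'
#' Probability weights for phantoms with 0, 1 and 2 inclusions
#' (1%, 44% and 55%).
#'
#' @return numeric vector of length 3 summing to 1.
#' @export
default_partition <- function() c(`0` = 0.01, `1` = 0.44, `2` = 0.55)

# containment margin used by the sampler: inclusions kept off the boundary
# source/detector ring
INCLUSION_MARGIN <- 0.95

#' Sample a random phantom from the parameter space
#'
#' Every scalar is drawn uniformly from its range; the number of inclusions
#' is drawn from \code{partition} (or forced via \code{n_inclusions}).
#' Inclusion placement is resampled (up to 100 attempts) until the inclusion
#' lies within 95% of the phantom radius and, with two inclusions, the discs
#' are disjoint.
#'
#' @param ranges parameter ranges, as \code{\link{default_ranges}}.
#' @param partition inclusion-count weights (0, 1, 2), summing to 1.
#' @param n_inclusions optional fixed inclusion count (overrides partition).
#' @return a \code{dot_phantom}. Consumes the R random stream (seed with
#'   \code{set.seed} for determinism).
#' @export
sample_phantom <- function(ranges = default_ranges(),
                           partition = default_partition(),
                           n_inclusions = NULL) {
  stopifnot(all(vapply(ranges, function(r) r[1] <= r[2], logical(1))))
  if (is.null(n_inclusions)) {
    stopifnot(length(partition) == 3, abs(sum(partition) - 1) < 1e-9)
    n_inclusions <- sample.int(3, 1, prob = partition) - 1L
  }
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  D <- runif1(ranges$diameter_mm)
  R <- D / 2
  f <- runif1(ranges$frequency_MHz)
  mu_a0 <- runif1(ranges$mu_a0)
  mu_s0 <- runif1(ranges$mu_s0)

  # Place the full inclusion configuration; if a partial configuration
  # becomes infeasible (e.g. a large first inclusion in a small phantom
  # leaves no room for a disjoint second), restart the whole configuration
  # rather than getting stuck on the accepted inclusion.
  incs <- list()
  for (restart in 1:25) {
    incs <- list()
    attempts <- 0L
    while (length(incs) < n_inclusions && attempts < 100L) {
      attempts <- attempts + 1L
      rad <- runif1(ranges$radius_mm)
      roc <- stats::runif(1, 0, R)
      th <- stats::runif(1, 0, 360)
      if (roc + rad > INCLUSION_MARGIN * R) next
      cand <- inclusion(rad, roc, th, runif1(ranges$contrast), runif1(ranges$contrast))
      ok <- TRUE
      for (other in incs) {   # two-inclusion phantoms: require disjoint discs
        d <- sqrt(sum((inclusion_center(cand) - inclusion_center(other))^2))
        if (d < cand$radius_mm + other$radius_mm) { ok <- FALSE; break }
      }
      if (ok) incs <- c(incs, list(cand))
    }
    if (length(incs) == n_inclusions) break
  }
  if (length(incs) < n_inclusions) {
    stop(sprintf(paste0("could not place %d inclusion(s) after bounded resampling ",
                        "(diameter %.3g mm, radius range [%.3g, %.3g])"),
                 n_inclusions, D, ranges$radius_mm[1], ranges$radius_mm[2]))
  }
  phantom(D, f, mu_a0, mu_s0, incs, margin = INCLUSION_MARGIN)
}

inclusion_center <- function(inc) {
  th <- inc$angle_deg * pi / 180
  inc$off_center_mm * c(cos(th), sin(th))
}

#' Stratified inclusion-count allocation
#'
#' Allocates exact inclusion counts for \code{n} samples according to the
#' partition weights (largest-remainder rounding), so a 10,000-sample draw
#' under the default partition yields exactly 100 / 4400 / 5500 phantoms
#' with 0 / 1 / 2 inclusions. The returned labels are in a fixed stratified
#' order; the dataset generator shuffles them under its seed.
#'
#' @param n number of samples.
#' @param partition weights for 0, 1, 2 inclusions.
#' @return integer vector of length n with values 0, 1, 2.
#' @export
allocate_inclusion_counts <- function(n, partition = default_partition()) {
  stopifnot(n >= 1, length(partition) == 3, abs(sum(partition) - 1) < 1e-9)
  exact <- n * partition
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(0:2, times = base)
}

#' Map a phantom onto mesh nodes
#'
#' A node whose coordinates fall inside an inclusion disc receives
#' background x contrast; all other nodes receive the background value.
#' Overlapping inclusions resolve to the maximum contrast.
#'
#' @param phantom a \code{dot_phantom}.
#' @param mesh a \code{dot_mesh} with the same diameter.
#' @return list with per-node vectors \code{mu_a} and \code{mu_s} (class
#'   \code{dot_coeffs}).
#' @export
nodal_coefficients <- function(phantom, mesh) {
  stopifnot(inherits(phantom, "dot_phantom"), inherits(mesh, "dot_mesh"))
  if (abs(phantom$diameter_mm - mesh$diameter_mm) > 1e-9 * phantom$diameter_mm) {
    stop("mesh diameter does not match phantom diameter")
  }
  co <- mesh$node_coords
  ca <- rep(1, nrow(co)); cs <- rep(1, nrow(co))
  for (inc in phantom$inclusions) {
    cen <- inclusion_center(inc)
    inside <- (co[, 1] - cen[1])^2 + (co[, 2] - cen[2])^2 <= inc$radius_mm^2
    ca[inside] <- pmax(ca[inside], inc$contrast_a)
    cs[inside] <- pmax(cs[inside], inc$contrast_s)
  }
  structure(list(mu_a = phantom$mu_a0 * ca, mu_s = phantom$mu_s0 * cs),
            class = "dot_coeffs")
}

#' Pixel-center grid coordinates for a coefficient image
#'
#' The 64 x 64 (or \code{grid_size}^2) grid spans [-d/2, d/2]^2 with pixel
#' centers at (i + 0.5)/grid_size of the span; row 1 is minimum y.
#'
#' @param grid_size pixels per side.
#' @param diameter_mm phantom diameter.
#' @return list with vectors \code{x}, \code{y} (pixel-center coordinates)
#'   and matrix \code{mask} (pixel center inside the inscribed circle).
#' @export
image_grid <- function(grid_size = 64L, diameter_mm) {
  stopifnot(grid_size >= 2)
  R <- diameter_mm / 2
  cc <- (-R) + diameter_mm * (seq_len(grid_size) - 0.5) / grid_size
  # mask[row, col] with row = y index, col = x index (circle, so symmetric)
  mask <- outer(cc, cc, function(y, x) x^2 + y^2 <= R^2)
  list(x = cc, y = cc, mask = mask)
}

#' Rasterize the ground-truth coefficient image of a phantom
#'
#' Draws the phantom and its inclusions as exact discs at pixel-center
#' resolution on a \code{grid_size} x \code{grid_size} grid spanning
#' [-d/2, d/2]^2. Pixels whose center lies outside the inscribed circle are
#' masked (value 0).
#'
#' @param phantom a \code{dot_phantom}.
#' @param grid_size pixels per side (default 64).
#' @param kind \code{"absolute"} for coefficient values (1/mm) or
#'   \code{"contrast"} for normalized contrast (mu/mu0 - 1)/(c_max - 1) in
#'   [0, 1].
#' @param c_max maximum contrast used for the contrast normalization.
#' @return a \code{dot_image}: list with 64 x 64 matrices \code{mu_a_grid},
#'   \code{mu_s_grid} (row = y index from minimum y, col = x index),
#'   logical \code{mask}, \code{kind}, \code{diameter_mm}, and the phantom
#'   backgrounds \code{mu_a0}, \code{mu_s0}.
#' @export
rasterize_truth <- function(phantom, grid_size = 64L, kind = c("absolute", "contrast"),
                            c_max = 8) {
  kind <- match.arg(kind)
  g <- image_grid(grid_size, phantom$diameter_mm)
  ca <- matrix(1, grid_size, grid_size)
  cs <- matrix(1, grid_size, grid_size)
  X <- matrix(g$x, grid_size, grid_size, byrow = TRUE)  # col = x
  Y <- matrix(g$y, grid_size, grid_size)                # row = y
  for (inc in phantom$inclusions) {
    cen <- inclusion_center(inc)
    inside <- (X - cen[1])^2 + (Y - cen[2])^2 <= inc$radius_mm^2
    ca[inside] <- pmax(ca[inside], inc$contrast_a)
    cs[inside] <- pmax(cs[inside], inc$contrast_s)
  }
  if (kind == "absolute") {
    ma <- phantom$mu_a0 * ca
    ms <- phantom$mu_s0 * cs
  } else {
    ma <- (ca - 1) / (c_max - 1)
    ms <- (cs - 1) / (c_max - 1)
  }
  ma[!g$mask] <- 0
  ms[!g$mask] <- 0
  structure(list(mu_a_grid = ma, mu_s_grid = ms, mask = g$mask, kind = kind,
                 diameter_mm = phantom$diameter_mm,
                 mu_a0 = phantom$mu_a0, mu_s0 = phantom$mu_s0),
            class = "dot_image")
}

#' Write phantom cases as a CSV table
#'
#' One row per phantom with columns CASE, D, f, mu_a, mu_s, and
#' bracket-packed per-inclusion r, r_oc, theta_oc, c_a, c_s columns.
#'
#' @param phantoms list of \code{dot_phantom}.
#' @param path output CSV path.
#' @param labels optional case labels.
#' @return invisibly, the path.
#' @export
export_phantoms <- function(phantoms, path, labels = NULL) {
  if (is.null(labels)) labels <- sprintf("A%d", seq_along(phantoms))
  pack <- function(v) if (length(v) == 0) "" else if (length(v) == 1)
    sprintf("%.6g", v) else paste0("[", paste(sprintf("%.6g", v), collapse = ", "), "]")
  rows <- lapply(seq_along(phantoms), function(i) {
    p <- phantoms[[i]]
    data.frame(CASE = labels[i], D = p$diameter_mm, f = p$frequency_MHz,
               mu_a = p$mu_a0, mu_s = p$mu_s0,
               r = pack(vapply(p$inclusions, `[[`, 0, "radius_mm")),
               r_oc = pack(vapply(p$inclusions, `[[`, 0, "off_center_mm")),
               theta_oc = pack(vapply(p$inclusions, `[[`, 0, "angle_deg")),
               c_a = pack(vapply(p$inclusions, `[[`, 0, "contrast_a")),
               c_s = pack(vapply(p$inclusions, `[[`, 0, "contrast_s")))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
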