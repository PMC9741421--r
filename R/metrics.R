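#' Mean squared error over masked pixels
#'
#' @param X reconstructed image (matrix).
#' @param X_true reference image.
#' @param mask logical matrix of pixels to include (default: all).
#' @return scalar MSE.
#' @export
mse_image <- function(X, X_true, mask = NULL) {
  if (!all(dim(X) == dim(X_true))) stop("image shapes do not match")
  if (is.null(mask)) mask <- array(TRUE, dim(X))
  if (!any(mask)) stop("empty mask")
  mean((X[mask] - X_true[mask])^2)
}

#' Region specification for resolution metrics
#'
#' Built from the ground-truth phantom: each inclusion region is the set of
#' pixels whose center lies inside the true inclusion disc; the background
#' region is every in-phantom pixel at least \code{back_margin_px} pixel
#' widths outside every inclusion disc.
#'
#' @param phantom the ground-truth \code{dot_phantom}.
#' @param grid_size image resolution (default 64).
#' @param percentile_high,percentile_low robust percentiles standing in for
#'   the max / min (defaults 90 and 10).
#' @param back_margin_px background standoff from the inclusions, in pixels.
#' @return a \code{dot_regions}: list of per-inclusion logical masks,
#'   background mask, and the percentile settings.
#' @export
region_spec <- function(phantom, grid_size = 64L,
                        percentile_high = 90, percentile_low = 10,
                        back_margin_px = 2) {
  g <- image_grid(grid_size, phantom$diameter_mm)
  X <- matrix(g$x, grid_size, grid_size, byrow = TRUE)
  Y <- matrix(g$y, grid_size, grid_size)
  px <- phantom$diameter_mm / grid_size
  incl <- list()
  back <- g$mask
  for (inc in phantom$inclusions) {
    cen <- inclusion_center(inc)
    d2 <- (X - cen[1])^2 + (Y - cen[2])^2
    incl <- c(incl, list(d2 <= inc$radius_mm^2 & g$mask))
    back <- back & (d2 > (inc$radius_mm + back_margin_px * px)^2)
  }
  structure(list(inclusion_masks = incl, background_mask = back,
                 percentile_high = percentile_high,
                 percentile_low = percentile_low, mask = g$mask),
            class = "dot_regions")
}

# robust Weber contrast of an image over the region spec:
# (mean over inclusions of P90_incl - P10_back) / P10_back
weber_contrast <- function(img, regions) {
  p10_back <- stats::quantile(img[regions$background_mask],
                              regions$percentile_low / 100, names = FALSE)
  p90s <- vapply(regions$inclusion_masks, function(m) {
    stats::quantile(img[m], regions$percentile_high / 100, names = FALSE)
  }, numeric(1))
  (mean(p90s) - p10_back) / p10_back
}

# fold a raw resolution ratio: identity below 1, reflected (2 - Ro) above,
# so that overestimation beyond a factor 2 turns negative
fold_resolution <- function(Ro) ifelse(Ro > 1, 2 - Ro, Ro)

#' Contrast resolution of a reconstruction
#'
#' Raw contrast resolution \code{Ro_cont} is the ratio of the robust Weber
#' contrasts (90th percentile over inclusions vs 10th percentile of
#' background) of the reconstruction and the truth; the folded value
#' \code{R_cont} reflects ratios above 1 (\code{2 - Ro}), so negative values
#' signal strong overestimation.
#'
#' @param recon reconstructed image (matrix, absolute coefficients or any
#'   positive rescaling; the measure is ratio-based).
#' @param truth ground-truth image on the same grid.
#' @param regions a \code{dot_regions}.
#' @return list with \code{Ro_cont} and \code{R_cont}.
#' @export
contrast_resolution <- function(recon, truth, regions) {
  if (length(regions$inclusion_masks) == 0) stop("no inclusion region defined")
  C_true <- weber_contrast(truth, regions)
  if (abs(C_true) < 1e-12) stop("truth has no contrast; case is homogeneous")
  Ro <- weber_contrast(recon, regions) / C_true
  list(Ro_cont = Ro, R_cont = fold_resolution(Ro))
}

#' Compose the size resolution from its factors
#'
#' \code{R_size = sqrt(Ro_size * R_cont)} when both factors are nonnegative.
#' On the negative branch the unfolded contrast ratio \code{2 - R_cont} is
#' substituted and the result carries a negative sign whenever either factor
#' is negative (the composition consistent with the worked resolution
#' tables).
#'
#' @param R_cont folded contrast resolution.
#' @param Ro_size raw size resolution.
#' @return composed size resolution.
#' @export
compose_size_resolution <- function(R_cont, Ro_size) {
  if (R_cont >= 0 && Ro_size >= 0) return(sqrt(Ro_size * R_cont))
  Rstar <- if (Ro_size < 0 || R_cont < 0) 2 - R_cont else R_cont
  -sqrt(abs(Ro_size) * abs(Rstar))
}

#' Size resolution of a reconstruction
#'
#' Raw size resolution
#' \code{Ro_size = 1 - RMSE(recon, truth | inclusions) / RMSE(truth, baseline | inclusions)},
#' where the baseline is the flat background coefficient; a reconstruction
#' that never departs from the background scores 0, perfect recovery scores
#' 1, negative values signal gross under/overestimation. The reported
#' \code{R_size} composes \code{Ro_size} with the contrast resolution (see
#' \code{\link{compose_size_resolution}}).
#'
#' @param recon,truth images on the same grid.
#' @param regions a \code{dot_regions}.
#' @param R_cont folded contrast resolution for the same pair.
#' @param baseline background coefficient value of the truth.
#' @return list with \code{Ro_size} and \code{R_size}.
#' @export
size_resolution <- function(recon, truth, regions, R_cont, baseline) {
  incl <- Reduce(`|`, regions$inclusion_masks)
  if (is.null(incl) || !any(incl)) stop("no inclusion region defined")
  rmse_recon <- sqrt(mean((recon[incl] - truth[incl])^2))
  rmse_base <- sqrt(mean((truth[incl] - baseline)^2))
  if (rmse_base < 1e-15) stop("zero baseline RMSE: truth has no contrast")
  Ro_size <- 1 - rmse_recon / rmse_base
  list(Ro_size = Ro_size, R_size = compose_size_resolution(R_cont, Ro_size))
}

#' Contrast-size-detail (CSD) resolution
#'
#' Signed geometric mean of the contrast and size resolutions:
#' \code{sqrt(R_cont * R_size)} when both are nonnegative; on the negative
#' branch the unfolded contrast \code{2 - R_cont} is substituted and the
#' magnitude of \code{R_size} is used under a negative sign.
#'
#' @param R_cont folded contrast resolution.
#' @param R_size composed size resolution.
#' @return scalar CSD resolution (1 = perfect; negative = overestimation).
#' @export
csd_resolution <- function(R_cont, R_size) {
  stopifnot(is.finite(R_cont), is.finite(R_size))
  if (R_cont >= 0 && R_size >= 0) return(sqrt(R_cont * R_size))
  -sqrt(abs(if (R_cont < 0 || R_size < 0) 2 - R_cont else R_cont) * abs(R_size))
}

#' Classify the raw contrast resolution against the detectability bound
#'
#' With maximum contrast \code{c_max}, a raw ratio above \code{1/c_max} is
#' "normal", exactly \code{1/c_max} is "no contrast", and below it
#' "abnormal" (the inclusion reads darker than its surround).
#'
#' @param Ro_cont raw contrast resolution.
#' @param c_max maximum contrast (default 8).
#' @return one of "normal", "no contrast", "abnormal".
#' @export
classify_contrast <- function(Ro_cont, c_max = 8) {
  stopifnot(c_max > 1)
  thr <- 1 / c_max
  if (Ro_cont > thr) "normal" else if (Ro_cont == thr) "no contrast" else "abnormal"
}

#' Full resolution report for one reconstructed sample
#'
#' Computes contrast, size and CSD resolutions for both coefficient channels
#' against the rasterized truth of the phantom, classifies the contrast, and
#' flags whether each resolution clears the reference threshold T (default
#' 0.3: at least 30% of the original contrast/size recovered).
#'
#' @param recon a \code{dot_image} with absolute coefficient grids.
#' @param truth a \code{dot_image} (absolute) for the same phantom, or NULL
#'   to rasterize from \code{phantom}.
#' @param phantom the ground-truth \code{dot_phantom}.
#' @param threshold reference value T (default 0.3).
#' @param c_max maximum contrast for classification.
#' @return a \code{dot_resolution_report}: per-coefficient rows of Ro_cont,
#'   R_cont, Ro_size, R_size, R_csd, classification and threshold flags; or
#'   a homogeneous-case marker when the phantom has no inclusions.
#' @export
evaluate_sample <- function(recon, truth = NULL, phantom, threshold = 0.3,
                            c_max = 8) {
  grid_size <- nrow(recon$mu_a_grid)
  if (is.null(truth)) truth <- rasterize_truth(phantom, grid_size, kind = "absolute")
  if (!all(dim(recon$mu_a_grid) == dim(truth$mu_a_grid))) stop("grid shapes differ")
  if (length(phantom$inclusions) == 0) {
    return(structure(list(homogeneous = TRUE, table = NULL), class = "dot_resolution_report"))
  }
  regions <- region_spec(phantom, grid_size)
  one <- function(rg, tg, baseline) {
    cr <- contrast_resolution(rg, tg, regions)
    sr <- size_resolution(rg, tg, regions, cr$R_cont, baseline)
    csd <- csd_resolution(cr$R_cont, sr$R_size)
    data.frame(Ro_cont = cr$Ro_cont, R_cont = cr$R_cont,
               Ro_size = sr$Ro_size, R_size = sr$R_size, R_csd = csd,
               classification = classify_contrast(cr$Ro_cont, c_max),
               pass_T = csd >= threshold)
  }
  tab <- rbind(cbind(coefficient = "mu_a",
                     one(recon$mu_a_grid, truth$mu_a_grid, phantom$mu_a0)),
               cbind(coefficient = "mu_s",
                     one(recon$mu_s_grid, truth$mu_s_grid, phantom$mu_s0)))
  structure(list(homogeneous = FALSE, table = tab, threshold = threshold),
            class = "dot_resolution_report")
}

#' @export
print.dot_resolution_report <- function(x, ...) {
  if (x$homogeneous) {
    cat("<dot_resolution_report> homogeneous case: contrast metrics undefined\n")
  } else {
    cat("<dot_resolution_report> (T =", x$threshold, ")\n")
    print(x$table, row.names = FALSE)
  }
  invisible(x)
}
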