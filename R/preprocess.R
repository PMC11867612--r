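#' Estimate a smooth background field for one channel
#'
#' Large-kernel Gaussian smoothing applied independently to each z-plane
#' (the stacks are only a few optical sections deep, so a tissue-scale
#' kernel is meaningful only in-plane). The stated `diameter_um` is treated
#' as the kernel full width at half maximum, so
#' `sigma = diameter_um / (2 * sqrt(2 * log(2)))`, converted to pixels via
#' the voxel size. Edges use normalized (renormalized-kernel) convolution,
#' so a constant image is preserved exactly and the operator is linear.
#'
#' @param channel 2D matrix or 3D array `[y, x, z]` of intensities.
#' @param voxel_size_um voxel size `(x, y)` or `(x, y, z)` in um.
#' @param diameter_um FWHM of the Gaussian kernel in um (default 50).
#' @return Smooth field, same shape as `channel`.
#' @export
estimate_background <- function(channel, voxel_size_um, diameter_um = 50) {
  check_scalar_num(diameter_um, "diameter_um", lower = 0, strict_lower = TRUE)
  vx <- voxel_size_um[1]; vy <- voxel_size_um[2]
  if (diameter_um < 2 * min(vx, vy)) {
    stopf("diameter_um (%g um) is below 2 pixels (%g um)", diameter_um,
          2 * min(vx, vy))
  }
  sigma_um <- diameter_um / (2 * sqrt(2 * log(2)))
  sx <- sigma_um / vx
  sy <- sigma_um / vy
  blur_fun <- function(m) gaussian_blur_2d(m, sx, sy)
  if (is.matrix(channel)) return(blur_fun(channel))
  stopifnot(length(dim(channel)) == 3L)
  out <- channel
  for (k in seq_len(dim(channel)[3])) out[, , k] <- blur_fun(channel[, , k])
  out
}

# Separable Gaussian blur of a matrix with per-row renormalized kernels
# (constant-preserving at edges). sigma in pixels along x (columns) and y
# (rows).
gaussian_blur_2d <- function(m, sigma_x, sigma_y) {
  blur_axis <- function(n, sigma) {
    if (sigma < 1e-8) return(NULL)
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
    r <- ceiling(4 * sigma)
    K[abs(outer(idx, idx, "-")) > r] <- 0
    K / rowSums(K)
  }
  Ky <- blur_axis(nrow(m), sigma_y)
  Kx <- blur_axis(ncol(m), sigma_x)
  if (!is.null(Ky)) m <- Ky %*% m
  if (!is.null(Kx)) m <- m %*% t(Kx)
  m
}

#' Subtract a background field, clipping at zero
#'
#' @param channel intensity array.
#' @param background field from [estimate_background()], same shape.
#' @return `pmax(channel - background, 0)`, elementwise.
#' @export
subtract_background <- function(channel, background) {
  if (!identical(dim(channel), dim(background))) {
    stopf("channel and background shapes differ")
  }
  out <- channel - background
  out[out < 0] <- 0
  out
}

#' Estimate an intensity threshold from square reference ROIs
#'
#' Pools all voxel intensities (across every z-plane) inside a set of square
#' in-plane ROIs and sets `threshold = median + k * SD` (sample SD, pooled),
#' following the convention of thresholding each image roughly one standard
#' deviation above the median of reference areas of varying punctum density.
#'
#' @param corrected background-corrected channel (2D matrix or 3D array).
#' @param voxel_size_um voxel size `(x, y[, z])` in um, used to convert ROI
#'   corners from um to pixels.
#' @param rois data.frame with columns `x_um`, `y_um` (ROI corner, um) and
#'   `side_px` (side length in pixels). When `NULL`, three default ROIs of
#'   `roi_side_px` pixels are spread along the horizontal midline of the
#'   image, sampling laterally varying punctum densities.
#' @param k multiplier on the pooled SD (default 1).
#' @param roi_side_px side of the default ROIs in pixels (default 50).
#' @return A `threshold_report`: list with `roi_specs`, `n_voxels`,
#'   `pooled_median`, `pooled_sd`, `k`, `threshold`.
#' @export
compute_intensity_threshold <- function(corrected, voxel_size_um, rois = NULL,
                                        k = 1, roi_side_px = 50) {
  check_scalar_num(k, "k")
  if (is.matrix(corrected)) corrected <- array(corrected, c(dim(corrected), 1L))
  d <- dim(corrected)
  ny <- d[1]; nx <- d[2]
  vx <- voxel_size_um[1]; vy <- voxel_size_um[2]
  if (is.null(rois)) {
    # three squares spread along the horizontal midline, so that images with
    # laterally varying punctum density contribute ROIs of various densities
    s <- min(roi_side_px, nx, ny)
    n_def <- 3L
    cx <- (2 * seq_len(n_def) - 1) / (2 * n_def) * nx
    rois <- data.frame(
      x_um = pmin(pmax(round(cx - s / 2), 0), nx - s) * vx,
      y_um = rep(round((ny - s) / 2), n_def) * vy,
      side_px = s)
  }
  if (nrow(rois) < 1L) stopf("at least one ROI is required")
  vals <- vector("list", nrow(rois))
  for (r in seq_len(nrow(rois))) {
    j0 <- floor(rois$x_um[r] / vx) + 1L
    i0 <- floor(rois$y_um[r] / vy) + 1L
    s <- as.integer(rois$side_px[r])
    if (s < 1L) stopf("ROI %d is empty", r)
    if (i0 < 1L || j0 < 1L || i0 + s - 1L > ny || j0 + s - 1L > nx) {
      stopf("ROI %d (corner %g, %g um, side %d px) is out of bounds",
            r, rois$x_um[r], rois$y_um[r], s)
    }
    vals[[r]] <- as.numeric(corrected[i0:(i0 + s - 1L), j0:(j0 + s - 1L), ])
  }
  pooled <- unlist(vals)
  med <- median(pooled)
  s <- if (length(pooled) > 1L) sd(pooled) else 0
  structure(list(roi_specs = rois, n_voxels = length(pooled),
                 pooled_median = med, pooled_sd = s, k = k,
                 threshold = med + k * s),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(
    "<threshold_report> %d ROIs, %d voxels: median %.4g + %g * SD %.4g = %.4g\n",
    nrow(x$roi_specs), x$n_voxels, x$pooled_median, x$k, x$pooled_sd,
    x$threshold))
  invisible(x)
}
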