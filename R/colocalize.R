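#' Detect regional maxima in the reporter (tdTomato) channel
#'
#' Lightly smooths the corrected reporter channel (Gaussian, sigma 0.25 um
#' by default) and returns every local maximum, with no intensity cutoff —
#' classification into signal and noise happens downstream at the bimodal
#' valley. The minimum-separation rule is the same greedy suppression used
#' for bouton seeds.
#'
#' @param corrected_tdt corrected reporter channel, 3D array `[y, x, z]`.
#' @param voxel_size_um voxel size `(x, y, z)` in um.
#' @param min_separation_um minimum peak separation (default 0.5 um).
#' @param smooth_sigma_um pre-smoothing sigma in um (default 0.25).
#' @return data.frame of maxima (`i, j, k`, `x_um, y_um, z_um`,
#'   `intensity` = smoothed value at the maximum).
#' @export
detect_tdt_maxima <- function(corrected_tdt, voxel_size_um,
                              min_separation_um = 0.5,
                              smooth_sigma_um = 0.25) {
  if (is.matrix(corrected_tdt)) {
    corrected_tdt <- array(corrected_tdt, c(dim(corrected_tdt), 1L))
  }
  sm <- smooth_3d(corrected_tdt, voxel_size_um, smooth_sigma_um)
  detect_peaks(sm, voxel_size_um, threshold = -Inf,
               min_separation_um = min_separation_um)
}

#' Assign each bouton a reporter intensity by nearest-maximum matching
#'
#' For every segmented bouton, the nearest reporter regional maximum within
#' `max_center_distance_um` (strictly `<=`, physical distance to the bouton
#' centroid) supplies `tdt_intensity` and sets `tdt_matched = TRUE`. Boutons
#' with no maximum in range fall back to the maximum corrected reporter
#' value inside their own voxel mask, with `tdt_matched = FALSE`; keeping
#' them in the intensity pool populates the noise mode of the bimodal
#' histogram.
#'
#' @param boutons a `bouton_set` from [segment_boutons()].
#' @param maxima reporter maxima from [detect_tdt_maxima()] on the same
#'   section.
#' @param corrected_tdt corrected reporter channel (for the mask fallback).
#' @param max_center_distance_um matching radius (default 0.7 um).
#' @return The `bouton_set` with `tdt_intensity` and `tdt_matched` filled.
#' @export
assign_tdt_intensity <- function(boutons, maxima, corrected_tdt,
                                 max_center_distance_um = 0.7) {
  tab <- boutons$table
  if (is.matrix(corrected_tdt)) {
    corrected_tdt <- array(corrected_tdt, c(dim(corrected_tdt), 1L))
  }
  if (!identical(dim(corrected_tdt), dim(boutons$labels))) {
    stopf("reporter channel shape does not match the segmentation")
  }
  n <- nrow(tab)
  if (n == 0L) return(boutons)
  matched <- logical(n)
  intens <- numeric(n)
  r2 <- max_center_distance_um^2
  mx <- maxima$x_um; my <- maxima$y_um; mz <- maxima$z_um
  for (b in seq_len(n)) {
    if (length(mx)) {
      d2 <- (mx - tab$x_um[b])^2 + (my - tab$y_um[b])^2 + (mz - tab$z_um[b])^2
      kbest <- which.min(d2)
      if (d2[kbest] <= r2) {
        matched[b] <- TRUE
        intens[b] <- maxima$intensity[kbest]
      }
    }
  }
  if (any(!matched)) {
    pos <- which(boutons$labels > 0L)
    lab <- boutons$labels[pos]
    mask_max <- vapply(split(corrected_tdt[pos], lab), max, numeric(1))
    unm <- which(!matched)
    intens[unm] <- mask_max[as.character(tab$id[unm])]
  }
  tab$tdt_intensity <- intens
  tab$tdt_matched <- matched
  boutons$table <- tab
  boutons
}

#' Valley threshold of a bimodal intensity distribution
#'
#' Kernel-density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of the per-bouton reporter intensities. When the KDE has at
#' least two modes, the threshold is the density minimum between the two
#' highest modes. A unimodal KDE triggers an Otsu fallback on the raw
#' values, flagged in the report and via a warning.
#'
#' @param values per-bouton reporter intensities pooled across an image set;
#'   at least 50 values are required (pool across sections if necessary).
#' @param n_kde number of KDE evaluation points (default 512).
#' @return A `bimodal_threshold_report`: `values_n`, `mode_locations` (the
#'   two highest modes, ascending), `valley`, `bimodality_ok`,
#'   `fallback_used`.
#' @export
find_bimodal_threshold <- function(values, n_kde = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 50L) {
    stopf(paste("need >= 50 intensity values to locate the bimodal valley;",
                "pool boutons across sections"))
  }
  kde <- density(values, bw = "nrd0", n = n_kde)
  y <- kde$y; x <- kde$x
  n <- length(y)
  is_mode <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  modes <- which(is_mode)
  if (length(modes) >= 2L) {
    top2 <- modes[order(-y[modes])][1:2]
    lo <- min(top2); hi <- max(top2)
    between <- lo:hi
    valley_idx <- between[which.min(y[between])]
    rep <- list(values_n = length(values),
                mode_locations = sort(x[top2]),
                valley = x[valley_idx],
                bimodality_ok = TRUE,
                fallback_used = FALSE)
  } else {
    warning("intensity distribution is unimodal; falling back to Otsu",
            call. = FALSE)
    rep <- list(values_n = length(values),
                mode_locations = if (length(modes)) x[modes] else numeric(),
                valley = otsu_threshold(values),
                bimodality_ok = FALSE,
                fallback_used = TRUE)
  }
  structure(rep, class = "bimodal_threshold_report")
}

# Otsu's threshold on a 256-bin histogram of the values.
otsu_threshold <- function(values, n_bins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h); total <- w[n_bins]
  mu <- cumsum(h * mids); mu_t <- mu[n_bins]
  w1 <- w[-n_bins]; w2 <- total - w1
  valid <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, n_bins - 1)
  bc[valid] <- (mu_t * w1[valid] - total * mu[-n_bins][valid])^2 /
    (w1[valid] * w2[valid])
  br[which.max(bc) + 1L]
}

#' @export
print.bimodal_threshold_report <- function(x, ...) {
  cat(sprintf(
    "<bimodal_threshold_report> n = %d, valley = %.4g (%s)\n", x$values_n,
    x$valley,
    if (x$bimodality_ok) {
      sprintf("modes %.4g / %.4g", x$mode_locations[1], x$mode_locations[2])
    } else "Otsu fallback"))
  invisible(x)
}

#' Classify boutons as reporter-positive
#'
#' A bouton counts as a putative PC bouton when it both matched a reporter
#' regional maximum within the colocalization radius and its assigned
#' intensity lies strictly above the valley threshold.
#'
#' @param boutons a `bouton_set` with `tdt_intensity` assigned.
#' @param report a `bimodal_threshold_report` (or a bare numeric valley).
#' @return The `bouton_set` with `is_pc` filled.
#' @export
classify_pc <- function(boutons, report) {
  valley <- if (inherits(report, "bimodal_threshold_report")) {
    report$valley
  } else {
    as.numeric(report)
  }
  tab <- boutons$table
  if (nrow(tab) && anyNA(tab$tdt_matched)) {
    stopf("tdt intensities not assigned; run assign_tdt_intensity() first")
  }
  tab$is_pc <- tab$tdt_matched & tab$tdt_intensity > valley
  boutons$table <- tab
  boutons
}
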