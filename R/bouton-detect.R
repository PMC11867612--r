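#' Find watershed seed points for punctum segmentation
#'
#' Local maxima of the background-corrected vGAT channel with intensity at or
#' above the detection threshold and pairwise physical separation of at
#' least one bouton diameter. Separation is enforced greedily from the
#' brightest candidate down (ties broken by lowest z, y, x index), so the
#' result is deterministic and respects voxel anisotropy.
#'
#' @param corrected_vgat background-corrected channel, 3D array `[y, x, z]`
#'   (a matrix is treated as a single plane).
#' @param voxel_size_um voxel size `(x, y, z)` in um.
#' @param threshold detection threshold (a.u.), typically from
#'   [compute_intensity_threshold()].
#' @param min_separation_um minimum seed separation, the nominal bouton
#'   diameter (default 1.0 um).
#' @return data.frame of seeds: voxel indices `i, j, k`, physical
#'   coordinates `x_um, y_um, z_um`, `intensity`.
#' @export
find_seed_maxima <- function(corrected_vgat, voxel_size_um, threshold,
                             min_separation_um = 1.0) {
  check_scalar_num(threshold, "threshold", lower = 0)
  check_scalar_num(min_separation_um, "min_separation_um", lower = 0)
  detect_peaks(corrected_vgat, voxel_size_um, threshold = threshold,
               min_separation_um = min_separation_um)
}

#' Segment boutons by marker-based watershed
#'
#' Runs a marker-based watershed on the inverted corrected channel,
#' restricted to voxels at or above the threshold, with one marker per seed.
#' Objects smaller than `min_voxels` are discarded. Per-object measurements
#' are reported in physical units: intensity-weighted centroid (um), volume
#' (voxels and um^3), peak and integrated corrected vGAT intensity.
#'
#' @param corrected_vgat corrected channel, as in [find_seed_maxima()].
#' @param voxel_size_um voxel size `(x, y, z)` in um.
#' @param seeds seed table from [find_seed_maxima()] on the same image.
#' @param threshold the same threshold used for the seeds.
#' @param min_voxels minimum object size in voxels (default 2; single-voxel
#'   specks are treated as noise).
#' @param section_id identifier copied into the table (default `"s1"`).
#' @return A `bouton_set`: list with `table` (one row per bouton: `id`,
#'   `section_id`, `x_um`, `y_um`, `z_um`, `volume_voxels`, `volume_um3`,
#'   `peak_vgat`, `integrated_vgat`, plus `tdt_intensity`, `tdt_matched`,
#'   `is_pc`, `region_id` columns filled by later stages), `labels` (integer
#'   array, same shape as the image, 0 = background), `voxel_size_um`,
#'   `threshold`.
#' @export
segment_boutons <- function(corrected_vgat, voxel_size_um, seeds, threshold,
                            min_voxels = 2L, section_id = "s1") {
  if (is.matrix(corrected_vgat)) {
    corrected_vgat <- array(corrected_vgat, c(dim(corrected_vgat), 1L))
  }
  d <- dim(corrected_vgat)
  empty <- data.frame(id = integer(), section_id = character(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      volume_voxels = integer(), volume_um3 = numeric(),
                      peak_vgat = numeric(), integrated_vgat = numeric(),
                      tdt_intensity = NA_real_[0], tdt_matched = logical(),
                      is_pc = logical(), region_id = integer())
  if (nrow(seeds) == 0L) {
    return(structure(list(table = empty, labels = array(0L, d),
                          voxel_size_um = voxel_size_um,
                          threshold = threshold),
                     class = "bouton_set"))
  }
  lin <- seeds$i + (seeds$j - 1L) * d[1] + (seeds$k - 1L) * d[1] * d[2]
  mask <- corrected_vgat >= threshold
  labels <- .cpp_watershed(as.numeric(-corrected_vgat), as.integer(d),
                           as.integer(lin), as.logical(mask))
  labels <- array(labels, d)

  nlab <- nrow(seeds)
  sizes <- tabulate(labels[labels > 0L], nbins = nlab)
  survivors <- which(sizes >= min_voxels)
  if (!length(survivors)) {
    return(structure(list(table = empty, labels = array(0L, d),
                          voxel_size_um = voxel_size_um,
                          threshold = threshold),
                     class = "bouton_set"))
  }
  # relabel sequentially; drop undersized objects
  remap <- integer(nlab)
  remap[survivors] <- seq_along(survivors)
  pos <- which(labels > 0L)
  newlab <- remap[labels[pos]]
  labels[pos] <- newlab
  pos <- pos[newlab > 0L]
  lab <- labels[pos]

  # physical coordinates of every labeled voxel
  kk <- (pos - 1L) %/% (d[1] * d[2]) + 1L
  rem <- (pos - 1L) %% (d[1] * d[2])
  jj <- rem %/% d[1] + 1L
  ii <- rem %% d[1] + 1L
  v <- corrected_vgat[pos]
  wsum <- rowsum(v, lab)[, 1]
  # centroid weights: intensity above the isolation threshold, so broad
  # suprathreshold skirts shared with neighbours do not bias localization
  w <- v - threshold
  wtot <- rowsum(w, lab)[, 1]
  wtot[wtot <= 0] <- 1
  cx <- rowsum(w * (jj - 0.5) * voxel_size_um[1], lab)[, 1] / wtot
  cy <- rowsum(w * (ii - 0.5) * voxel_size_um[2], lab)[, 1] / wtot
  cz <- rowsum(w * (kk - 0.5) * voxel_size_um[3], lab)[, 1] / wtot
  vol <- tabulate(lab, nbins = length(survivors))
  peak <- vapply(split(v, lab), max, numeric(1))
  vox_um3 <- prod(voxel_size_um)

  tab <- data.frame(
    id = seq_along(survivors),
    section_id = section_id,
    x_um = cx, y_um = cy, z_um = cz,
    volume_voxels = vol,
    volume_um3 = vol * vox_um3,
    peak_vgat = as.numeric(peak),
    integrated_vgat = as.numeric(wsum),
    tdt_intensity = NA_real_,
    tdt_matched = NA,
    is_pc = NA,
    region_id = NA_integer_,
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, labels = labels,
                 voxel_size_um = voxel_size_um, threshold = threshold),
            class = "bouton_set")
}

#' @export
print.bouton_set <- function(x, ...) {
  cat(sprintf("<bouton_set> %d boutons (threshold %.4g)\n",
              nrow(x$table), x$threshold))
  invisible(x)
}
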