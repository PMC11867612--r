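# Shared fixtures and independent oracles.

# Small, fast scene: ~46 x 46 x 1.5 um, two regions (dense / moderate).
small_scene_config <- function(seed = 0,
                               vgat_density_per_region = c(0.06, 0.04),
                               pc_fraction_per_region = c(0.7, 0.25),
                               ...) {
  scene_config(
    shape_voxels = c(128, 128, 5),
    region_layout = data.frame(
      region_id = c(1L, 2L), name = c("A", "B"),
      x0_um = c(3, 25), y0_um = c(3, 3),
      width_um = c(18, 18), height_um = c(40, 40)),
    vgat_density_per_region = vgat_density_per_region,
    pc_fraction_per_region = pc_fraction_per_region,
    seed = seed, ...)
}

# Render one or more Gaussian spots onto an empty array without noise.
render_spots <- function(dim_yx_z = c(32, 32, 5), centers_um, peaks,
                         fwhm_um = 1.0,
                         voxel_size_um = c(0.3611, 0.3611, 0.3)) {
  sigma <- rep(fwhm_um / (2 * sqrt(2 * log(2))), 3)
  boutonmap:::add_spots(array(0, dim_yx_z), as.matrix(centers_um), peaks,
                        sigma, voxel_size_um)
}

# Dense direct-convolution oracle for the constant-preserving Gaussian blur:
# per output pixel, weights over all input pixels, renormalized. O(n^4) --
# only for small images.
blur_oracle_2d <- function(m, sigma_x, sigma_y) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r <- ceiling(4 * max(sigma_x, sigma_y))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - r):min(nr, i + r)
    jj <- max(1, j - r):min(nc, j + r)
    w <- exp(-outer((ii - i)^2 / (2 * sigma_y^2),
                    (jj - j)^2 / (2 * sigma_x^2), "+"))
    w[outer(abs(ii - i) > r, rep(TRUE, length(jj)))] <- 0
    w[outer(rep(TRUE, length(ii)), abs(jj - j) > r)] <- 0
    out[i, j] <- sum(w * m[ii, jj]) / sum(w)
  }
  out
}

# Greedy minimum-separation suppression oracle (plain R double loop).
suppress_oracle <- function(coords, min_sep) {
  keep <- logical(nrow(coords))
  acc <- NULL
  for (i in seq_len(nrow(coords))) {
    ok <- TRUE
    if (!is.null(acc)) {
      d2 <- rowSums(sweep(acc, 2, coords[i, ])^2)
      if (any(d2 < min_sep^2)) ok <- FALSE
    }
    if (ok) {
      keep[i] <- TRUE
      acc <- rbind(acc, coords[i, , drop = FALSE])
    }
  }
  keep
}

# Build a bouton_set by hand for colocalization unit tests.
manual_bouton_set <- function(centroids_um, labels_dim = c(48, 48, 5),
                              voxel_size_um = c(0.3611, 0.3611, 0.3)) {
  n <- nrow(centroids_um)
  labels <- array(0L, labels_dim)
  for (b in seq_len(n)) {
    j <- floor(centroids_um[b, 1] / voxel_size_um[1]) + 1
    i <- floor(centroids_um[b, 2] / voxel_size_um[2]) + 1
    k <- floor(centroids_um[b, 3] / voxel_size_um[3]) + 1
    labels[i, j, k] <- b
    labels[i, j, min(k + 1, labels_dim[3])] <- b
  }
  tab <- data.frame(
    id = seq_len(n), section_id = "s1",
    x_um = centroids_um[, 1], y_um = centroids_um[, 2],
    z_um = centroids_um[, 3],
    volume_voxels = 2L, volume_um3 = 2 * prod(voxel_size_um),
    peak_vgat = 100, integrated_vgat = 150,
    tdt_intensity = NA_real_, tdt_matched = NA, is_pc = NA,
    region_id = NA_integer_)
  structure(list(table = tab, labels = labels,
                 voxel_size_um = voxel_size_um, threshold = 10),
            class = "bouton_set")
}

# Wilcoxon rank-sum U for group x, brute force.
u_stat_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# printed per-section LC counts: 0/27 responders anterior, 2/40 posterior
lc_fixture <- function() {
  data.frame(
    cell_id = sprintf("c%03d", 1:67),
    section_id = rep(c("ant", "post"), c(27, 40)),
    x_um = 0, y_um = 0,
    region_id = "LC",
    responded = c(rep(FALSE, 27), rep(TRUE, 2), rep(FALSE, 38)),
    amplitude_pa = c(rep(0, 27), 45, 55, rep(0, 38)),
    stringsAsFactors = FALSE)
}
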