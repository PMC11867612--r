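# Local-maxima detection shared by bouton seeding and reporter-channel
# regional maxima.

# 26-connected local maxima of a 3D array (pure-R reference used as an
# exhaustive-scan oracle in the tests; detect_peaks runs the compiled
# version). A voxel qualifies when it is >= every neighbour and > at least
# one neighbour, so constant plateaus (and an all-zero field) yield no
# maxima, while the rim voxels of a genuine peak plateau do qualify and are
# later merged by the separation rule.
local_maxima_3d <- function(arr) {
  d <- dim(arr)
  ny <- d[1]; nx <- d[2]; nz <- d[3]
  pad_lo <- array(-Inf, d + 2L)
  pad_hi <- array(Inf, d + 2L)
  core <- arr
  pad_lo[2:(ny + 1), 2:(nx + 1), 2:(nz + 1)] <- core
  pad_hi[2:(ny + 1), 2:(nx + 1), 2:(nz + 1)] <- core
  nmax <- array(-Inf, d)
  nmin <- array(Inf, d)
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    sub_lo <- pad_lo[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx),
                     (2 + dz):(nz + 1 + dz), drop = FALSE]
    sub_hi <- pad_hi[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx),
                     (2 + dz):(nz + 1 + dz), drop = FALSE]
    nmax <- pmax(nmax, sub_lo)
    nmin <- pmin(nmin, sub_hi)
  }
  which(core >= nmax & core > nmin)
}

# Isotropic-in-um Gaussian smoothing of a 3D array: separable, per-plane in
# xy then along z, edge-renormalized (constant-preserving).
smooth_3d <- function(arr, voxel_size_um, sigma_um) {
  if (sigma_um <= 0) return(arr)
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  d <- dim(arr)
  sx <- sigma_um / voxel_size_um[1]
  sy <- sigma_um / voxel_size_um[2]
  out <- arr
  for (k in seq_len(d[3])) out[, , k] <- gaussian_blur_2d(arr[, , k], sx, sy)
  sz <- sigma_um / voxel_size_um[3]
  if (d[3] > 1L && sz >= 1e-8) {
    flat <- matrix(out, nrow = d[1] * d[2], ncol = d[3])
    Kz <- exp(-outer(seq_len(d[3]), seq_len(d[3]), "-")^2 / (2 * sz^2))
    Kz <- Kz / rowSums(Kz)
    out <- array(flat %*% t(Kz), d)
  }
  out
}

# Detect peaks: local maxima above `threshold`, then greedy suppression so
# surviving peaks are pairwise >= min_separation_um apart in physical um
# (anisotropy respected). Candidates ranked by intensity, ties broken by
# lowest (z, y, x) index for determinism. Returns a data.frame with voxel
# indices (i = y row, j = x col, k = z plane), physical coordinates of the
# voxel center, and the intensity.
detect_peaks <- function(arr, voxel_size_um, threshold = -Inf,
                         min_separation_um = 0) {
  if (is.matrix(arr)) arr <- array(arr, c(dim(arr), 1L))
  idx <- .cpp_local_maxima(as.numeric(arr), as.integer(dim(arr)))
  if (length(idx)) idx <- idx[arr[idx] >= threshold]
  if (!length(idx)) {
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      x_um = numeric(), y_um = numeric(), z_um = numeric(),
                      intensity = numeric()))
  }
  d <- dim(arr)
  k <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  rem <- (idx - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1] + 1L
  i <- rem %% d[1] + 1L
  val <- arr[idx]
  ord <- order(-val, k, i, j)
  i <- i[ord]; j <- j[ord]; k <- k[ord]; val <- val[ord]
  x <- (j - 0.5) * voxel_size_um[1]
  y <- (i - 0.5) * voxel_size_um[2]
  z <- (k - 0.5) * voxel_size_um[3]
  if (min_separation_um > 0 && length(val) > 1L) {
    keep <- .cpp_suppress_min_sep(cbind(x, y, z), min_separation_um)
  } else {
    keep <- rep(TRUE, length(val))
  }
  out <- data.frame(i = i, j = j, k = k, x_um = x, y_um = y, z_um = z,
                    intensity = val)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
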