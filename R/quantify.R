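#' Bin bouton positions onto a coarse voxel grid
#'
#' Half-open binning of atlas-space bouton coordinates into voxels of
#' `bin_size_um` (default 144 x 144 x 4 um^3), anchored at `origin_um` with
#' 0-based bin indices: a point with `x = origin + i * w` falls in bin
#' `i` (lower edge closed, upper edge open). The in-plane density per bin is
#' `count / (bin_x * bin_y)` in boutons/um^2.
#'
#' @param points_um n x 3 matrix (or data.frame with `x_um`, `y_um`,
#'   `z_um`) of coordinates in um.
#' @param bin_size_um voxel size `(x, y, z)` in um (default `c(144, 144, 4)`).
#' @param origin_um grid origin (default `c(0, 0, 0)`).
#' @param extent_um optional `(x, y, z)` physical extent; when omitted the
#'   grid is sized to cover the points.
#' @return A `voxel_grid`: list with `origin_um`, `bin_size_um`, `counts`
#'   (3D array indexed `[ix, iy, iz]`), `density` (same shape, boutons/um^2
#'   of in-plane bin area), `n_sections_averaged = 1`.
#' @export
bin_to_grid <- function(points_um, bin_size_um = c(144, 144, 4),
                        origin_um = c(0, 0, 0), extent_um = NULL) {
  P <- as_points3(points_um)
  if (nrow(P) && !all(is.finite(P))) stopf("point coordinates must be finite")
  w <- as.numeric(bin_size_um)
  if (length(w) != 3L || any(w <= 0)) stopf("'bin_size_um' must be 3 positive numbers")
  o <- as.numeric(origin_um)
  idx <- sweep(sweep(P, 2, o), 2, w, "/")
  idx <- floor(idx + 1e-9)                 # guard against FP edge jitter
  if (nrow(P) && any(idx < 0)) stopf("points below the grid origin")
  if (is.null(extent_um)) {
    nbin <- pmax(apply(idx, 2, function(v) if (length(v)) max(v) + 1 else 1), 1)
  } else {
    nbin <- pmax(ceiling(as.numeric(extent_um) / w - 1e-9), 1)
    if (nrow(P) && any(idx >= rep(nbin, each = nrow(P)))) {
      stopf("points outside the stated grid extent")
    }
  }
  counts <- array(0L, nbin)
  if (nrow(P)) {
    lin <- idx[, 1] + nbin[1] * (idx[, 2] + nbin[2] * idx[, 3]) + 1
    t <- tabulate(lin, nbins = prod(nbin))
    counts <- array(as.integer(t), nbin)
  }
  new_voxel_grid(o, w, counts, n_sections_averaged = 1L)
}

new_voxel_grid <- function(origin_um, bin_size_um, counts,
                           n_sections_averaged) {
  structure(list(origin_um = origin_um, bin_size_um = bin_size_um,
                 counts = counts,
                 density = counts / (bin_size_um[1] * bin_size_um[2]),
                 n_sections_averaged = n_sections_averaged),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d bins of %g x %g x %g um^3, total count %g (%d section(s))\n",
    d[1], d[2], d[3], x$bin_size_um[1], x$bin_size_um[2], x$bin_size_um[3],
    sum(x$counts), x$n_sections_averaged))
  invisible(x)
}

#' Average voxel grids across sections
#'
#' Per-bin mean of the counts of several sections' grids (plain mean, not
#' density-weighted). All grids must share origin, bin size and shape.
#'
#' @param grids list of `voxel_grid` objects.
#' @return A `voxel_grid` of mean counts with `n_sections_averaged` set.
#' @export
average_grids <- function(grids) {
  if (!length(grids)) stopf("no grids supplied")
  g1 <- grids[[1]]
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g$origin_um, g1$origin_um)) ||
        !isTRUE(all.equal(g$bin_size_um, g1$bin_size_um)) ||
        !identical(dim(g$counts), dim(g1$counts))) {
      stopf("grids have mismatched geometry")
    }
  }
  mean_counts <- Reduce(`+`, lapply(grids, function(g) g$counts)) /
    length(grids)
  new_voxel_grid(g1$origin_um, g1$bin_size_um, mean_counts,
                 n_sections_averaged = length(grids))
}

#' Per-region bouton counts, densities and PC fractions
#'
#' Summarizes a classified bouton table by region: total GABAergic (vGAT)
#' boutons, reporter-positive (PC) boutons, region area, PC areal density
#' (`n_pc / area_um2`, boutons/um^2 treating the thin stack as one optical
#' section) and PC fraction (`n_pc / n_vgat`, `NA` when a region holds no
#' vGAT boutons). Boutons outside every region are reported under the
#' background id 0, whose area is the unlabeled area of the map.
#'
#' @param bouton_table data.frame with at least `region_id` and `is_pc`
#'   columns (a `bouton_set$table` after [classify_pc()] and region
#'   assignment).
#' @param map a [region_map()] supplying region areas; every map region is
#'   reported even when empty.
#' @return data.frame with one row per region: `region_id`, `name`,
#'   `n_vgat`, `n_pc`, `area_um2`, `pc_density_per_um2`, `pc_fraction`.
#' @export
summarize_regions <- function(bouton_table, map) {
  ids <- map$id_to_area_um2$region_id
  all_ids <- sort(unique(c(0L, ids, bouton_table$region_id)))
  n_vgat <- vapply(all_ids, function(id) {
    sum(bouton_table$region_id == id, na.rm = TRUE)
  }, integer(1))
  n_pc <- vapply(all_ids, function(id) {
    sum(bouton_table$is_pc & bouton_table$region_id == id, na.rm = TRUE)
  }, integer(1))
  px_area <- prod(map$pixel_size_um)
  bg_area <- sum(map$labels == 0L) * px_area
  area <- region_area(map, all_ids)
  area[all_ids == 0L] <- bg_area
  nm <- map$id_to_name$name[match(all_ids, map$id_to_name$region_id)]
  nm[all_ids == 0L] <- "background"
  out <- data.frame(
    region_id = all_ids, name = nm, n_vgat = n_vgat, n_pc = n_pc,
    area_um2 = area,
    pc_density_per_um2 = ifelse(area > 0, n_pc / area, 0),
    pc_fraction = ifelse(n_vgat > 0, n_pc / n_vgat, NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

as_points3 <- function(points_um) {
  if (is.data.frame(points_um)) {
    cols <- intersect(c("x_um", "y_um", "z_um"), names(points_um))
    if (length(cols) >= 2L) {
      P <- as.matrix(points_um[cols])
      if (!"z_um" %in% cols) P <- cbind(P, 0)
      return(P)
    }
    points_um <- as.matrix(points_um)
  }
  P <- as.matrix(points_um)
  if (ncol(P) == 2L) P <- cbind(P, 0)
  storage.mode(P) <- "double"
  P[, 1:3, drop = FALSE]
}
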