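#' Two-channel image stack with physical voxel geometry
#'
#' Container for a 3D multi-channel intensity volume. Arrays are indexed
#' `[y, x, z]` (row = y, column = x, plane = z); the center of voxel
#' `(i, j, k)` sits at physical coordinates
#' `((j - 0.5) * vx, (i - 0.5) * vy, (k - 0.5) * vz)` micrometres.
#'
#' @param channels named list of 3D numeric arrays, all the same dimension,
#'   all intensities finite and `>= 0`.
#' @param voxel_size_um numeric length-3 `(x, y, z)` voxel size in um, all
#'   `> 0`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels))) {
    stopf("'channels' must be a non-empty named list of 3D arrays")
  }
  d <- dim(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.array(ch) || length(dim(ch)) != 3L) {
      stopf("channel '%s' is not a 3D array", nm)
    }
    if (!identical(dim(ch), d)) stopf("channel '%s' has mismatched dimensions", nm)
    if (!all(is.finite(ch)) || any(ch < 0)) {
      stopf("channel '%s' has non-finite or negative intensities", nm)
    }
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || !all(is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stopf("'voxel_size_um' must be three positive numbers (x, y, z)")
  }
  structure(list(channels = channels, voxel_size_um = voxel_size_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d channel(s): %s\n",
              d[2], d[1], d[3], length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size %g x %g x %g um\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Region label map
#'
#' 2D integer label image with id -> name lookup and per-region areas.
#' Label 0 is background and never appears in the id table.
#'
#' @param labels integer matrix `[y, x]`; 0 = background.
#' @param pixel_size_um length-2 `(x, y)` pixel size in um.
#' @param id_to_name data.frame with columns `region_id`, `name`.
#' @return An object of class `region_map` with a precomputed
#'   `id_to_area_um2` table (pixel count times pixel area).
#' @export
region_map <- function(labels, pixel_size_um, id_to_name = NULL) {
  if (!is.matrix(labels)) stopf("'labels' must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stopf("region labels must be >= 0")
  pixel_size_um <- as.numeric(pixel_size_um)
  if (length(pixel_size_um) != 2L || any(pixel_size_um <= 0)) {
    stopf("'pixel_size_um' must be two positive numbers (x, y)")
  }
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  if (is.null(id_to_name)) {
    id_to_name <- data.frame(region_id = ids,
                             name = as.character(ids),
                             stringsAsFactors = FALSE)
  }
  px_area <- prod(pixel_size_um)
  counts <- tabulate(labels[labels > 0L], nbins = max(c(0L, ids)))
  areas <- data.frame(region_id = ids,
                      area_um2 = counts[ids] * px_area)
  structure(list(labels = labels, pixel_size_um = pixel_size_um,
                 id_to_name = id_to_name, id_to_area_um2 = areas),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> %d x %d px (%g x %g um/px), %d region(s)\n",
              ncol(x$labels), nrow(x$labels),
              x$pixel_size_um[1], x$pixel_size_um[2],
              nrow(x$id_to_area_um2)))
  invisible(x)
}

# region area lookup (um^2); 0 for unknown ids
region_area <- function(map, ids) {
  out <- numeric(length(ids))
  m <- match(ids, map$id_to_area_um2$region_id)
  ok <- !is.na(m)
  out[ok] <- map$id_to_area_um2$area_um2[m[ok]]
  out
}
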