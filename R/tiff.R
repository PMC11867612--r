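# Minimal baseline TIFF I/O (little-endian, uncompressed, single-sample
# grayscale). No TIFF package ships with the target environment, and the
# pipeline only needs flat multi-page stacks (float32 images, uint16 label
# maps), so a small self-contained reader/writer is used. Pages are written
# one strip each; readers of the output (e.g. tifffile, ImageJ) see plain
# baseline TIFF.

#' Write a multi-page grayscale TIFF
#'
#' @param pages a matrix, a 3D array `[y, x, page]`, or a list of matrices.
#' @param path output file.
#' @param format `"float32"` (default) or `"uint16"` (values are rounded and
#'   clamped to 0..65535).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, format = c("float32", "uint16")) {
  format <- match.arg(format)
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L) {
    pages <- lapply(seq_len(dim(pages)[3]), function(k) pages[, , k])
  }
  stopifnot(is.list(pages), length(pages) >= 1L)
  bps <- if (format == "float32") 32L else 16L
  sfmt <- if (format == "float32") 3L else 1L
  bytes_px <- bps / 8L

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header: II, magic 42, first IFD at offset 8
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(8L)
  offset <- 8L
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    data_bytes <- h * w * bytes_px
    data_off <- offset + ifd_size
    next_ifd <- if (p < length(pages)) data_off + data_bytes else 0L
    w16(n_entries)
    entry(256L, 3L, 1L, w)            # ImageWidth
    entry(257L, 3L, 1L, h)            # ImageLength
    entry(258L, 3L, 1L, bps)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression = none
    entry(262L, 3L, 1L, 1L)           # Photometric = BlackIsZero
    entry(273L, 4L, 1L, data_off)     # StripOffsets
    entry(278L, 3L, 1L, h)            # RowsPerStrip
    entry(279L, 4L, 1L, data_bytes)   # StripByteCounts
    entry(339L, 3L, 1L, sfmt)         # SampleFormat
    w32(next_ifd)
    v <- as.vector(t(m))              # row-major
    if (format == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- pmin(pmax(round(v), 0), 65535)
      # writeBin has no uint16; emit raw bytes
      iv <- as.integer(v)
      writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
    }
    offset <- if (p < length(pages)) next_ifd else 0L
  }
  invisible(path)
}

#' Read a TIFF written by [write_tiff()]
#'
#' Supports little-endian uncompressed grayscale pages (uint8/16/32 or
#' float32), the subset this package emits.
#'
#' @param path TIFF file.
#' @return list of matrices, one per page.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) {
    as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  }
  u32 <- function(off) {
    as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
      65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  }
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L) {
    stopf("not a little-endian TIFF")
  }
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      base <- ifd + 2 + (e - 1) * 12
      tag <- u16(base); type <- u16(base + 2)
      val <- if (type == 3L) u16(base + 8) else u32(base + 8)
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bps <- if (is.null(tags[["258"]])) 1L else tags[["258"]]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    sfmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]]
    if (comp != 1L) stopf("compressed TIFF not supported")
    off <- tags[["273"]]
    nb <- tags[["279"]]
    seg <- raw[(off + 1):(off + nb)]
    vals <- if (sfmt == 3L && bps == 32L) {
      readBin(seg, "double", n = w * h, size = 4, endian = "little")
    } else if (bps == 16L) {
      readBin(seg, "integer", n = w * h, size = 2, signed = FALSE,
              endian = "little")
    } else if (bps == 8L) {
      as.integer(seg)
    } else if (bps == 32L) {
      readBin(seg, "integer", n = w * h, size = 4, endian = "little")
    } else stopf("unsupported TIFF sample layout (bps %d, format %d)",
                 bps, sfmt)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  pages
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z-planes of channel 1, then channel
#' 2, ...); the sidecar (`<path>.json`) records channel names, plane count,
#' voxel size and an optional seed so the stack can be reassembled.
#'
#' @param stack an [image_stack()].
#' @param path TIFF output path.
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, seed = NULL) {
  nz <- dim(stack$channels[[1]])[3]
  pages <- list()
  for (ch in stack$channels) {
    for (k in seq_len(nz)) pages[[length(pages) + 1L]] <- ch[, , k]
  }
  write_tiff(pages, path, format = "float32")
  meta <- list(channel_names = names(stack$channels), n_planes = nz,
               voxel_size_um = stack$voxel_size_um,
               page_order = "channel-major")
  if (!is.null(seed)) meta$seed <- seed
  write_json_file(meta, paste0(path, ".json"))
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (expects the `<path>.json` sidecar next to it).
#' @return An [image_stack()].
#' @export
read_stack_tiff <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing sidecar '%s'", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- read_tiff(path)
  nz <- meta$n_planes
  chs <- list()
  for (c_i in seq_along(meta$channel_names)) {
    arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[(c_i - 1) * nz + k]]
    chs[[meta$channel_names[c_i]]] <- arr
  }
  image_stack(chs, meta$voxel_size_um)
}
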