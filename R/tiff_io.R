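# Minimal baseline-TIFF I/O for single-channel z-stacks.
#
# Scope: grayscale, uncompressed, one sample per pixel, 8- or 16-bit
# unsigned, multi-page; little- and big-endian on read, little-endian
# 16-bit on write.  This covers the stacks this package emits and plain
# exports from Fiji/tifffile; anything fancier (compression, tiles,
# RGB, planar configs) is rejected with a clear error.

.tiff_u16 <- function(x) {
  x <- as.integer(round(x))
  ifelse(x > 32767L, x - 65536L, x)
}

.wr_u16 <- function(con, x) writeBin(.tiff_u16(x), con, size = 2L, endian = "little")
.wr_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4L, endian = "little")

#' Write a z-stack as a multi-page 16-bit TIFF
#'
#' Pages are z slices in order; intensities are rounded and clamped to
#' the unsigned 16-bit range.
#'
#' @param stack an [image_stack] or a 3D numeric array `(nz, ny, nx)`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  arr <- as_stack_array(stack)
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  arr <- pmin(pmax(round(arr), 0), 65535)
  page_bytes <- 2L * nx * ny
  data_start <- 8L
  ifd0 <- data_start + nz * page_bytes
  n_entries <- 10L
  ifd_size <- 2L + 12L * n_entries + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  .wr_u16(con, 42L)
  .wr_u32(con, ifd0)
  for (z in seq_len(nz)) {
    # TIFF scanlines: rows top-to-bottom (y), pixels left-to-right (x)
    .wr_u16(con, as.vector(t(arr[z, , ])))
  }
  entry <- function(tag, type, value) {
    .wr_u16(con, tag); .wr_u16(con, type); .wr_u32(con, 1L)
    if (type == 3L) { .wr_u16(con, value); .wr_u16(con, 0L) } else .wr_u32(con, value)
  }
  for (z in seq_len(nz)) {
    .wr_u16(con, n_entries)
    entry(256L, 4L, nx)                               # ImageWidth
    entry(257L, 4L, ny)                               # ImageLength
    entry(258L, 3L, 16L)                              # BitsPerSample
    entry(259L, 3L, 1L)                               # Compression: none
    entry(262L, 3L, 1L)                               # Photometric: BlackIsZero
    entry(273L, 4L, data_start + (z - 1L) * page_bytes)  # StripOffsets
    entry(277L, 3L, 1L)                               # SamplesPerPixel
    entry(278L, 4L, ny)                               # RowsPerStrip
    entry(279L, 4L, page_bytes)                       # StripByteCounts
    entry(339L, 3L, 1L)                               # SampleFormat: unsigned
    .wr_u32(con, if (z < nz) ifd0 + z * ifd_size else 0L)  # next IFD
  }
  invisible(path)
}

.rd_int <- function(raw, offset, size, endian, n = 1L) {
  readBin(raw[(offset + 1L):(offset + size * n)], "integer",
          n = n, size = size, signed = size == 4L, endian = endian)
}

#' Read a grayscale multi-page TIFF as a z-stack
#'
#' @param path TIFF file path.
#' @param voxel_size physical voxel dimensions passed to [image_stack]
#'   (TIFF files do not carry calibrated z-step information).
#' @return an [image_stack] whose pages become z slices.
#' @export
read_stack_tiff <- function(path, voxel_size = c(z = 0.2, y = 0.0542, x = 0.0542)) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  if (.rd_int(raw, 2L, 2L, endian) != 42L) stop("bad TIFF magic in ", path, call. = FALSE)
  ifd_off <- .rd_int(raw, 4L, 4L, endian)

  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- .rd_int(raw, ifd_off, 2L, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2L + 12L * (i - 1L)
      tag <- .rd_int(raw, e, 2L, endian)
      type <- .rd_int(raw, e + 2L, 2L, endian)
      count <- .rd_int(raw, e + 4L, 4L, endian)
      type_size <- c(1L, 1L, 2L, 4L)[match(type, c(1L, 2L, 3L, 4L))]
      if (is.na(type_size)) { tags[[as.character(tag)]] <- NA; next }
      total <- type_size * count
      val_off <- if (total <= 4L) e + 8L else .rd_int(raw, e + 8L, 4L, endian)
      tags[[as.character(tag)]] <- .rd_int(raw, val_off, type_size, endian, n = count)
    }
    gettag <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- gettag(256L); h <- gettag(257L)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions", call. = FALSE)
    bits <- gettag(258L, 1L)[1]
    if (!bits %in% c(8L, 16L)) stop("unsupported BitsPerSample: ", bits, call. = FALSE)
    if (gettag(259L, 1L)[1] != 1L) stop("compressed TIFF not supported", call. = FALSE)
    if (gettag(277L, 1L)[1] != 1L) stop("multi-sample TIFF not supported", call. = FALSE)
    offsets <- gettag(273L); counts <- gettag(279L)
    if (is.null(offsets)) stop("TIFF page missing strip offsets", call. = FALSE)
    if (is.null(counts)) counts <- rep(2L * w * h / length(offsets), length(offsets))
    vals <- unlist(lapply(seq_along(offsets), function(i) {
      .rd_int(raw, offsets[i], bits %/% 8L, endian, n = counts[i] %/% (bits %/% 8L))
    }), use.names = FALSE)
    if (bits == 16L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
    else vals <- ifelse(vals < 0L, vals + 256L, vals)
    pages[[length(pages) + 1L]] <- matrix(vals[seq_len(w * h)], ncol = w, byrow = TRUE)
    ifd_off <- .rd_int(raw, ifd_off + 2L + 12L * n_entries, 4L, endian)
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  image_stack(arr, voxel_size = voxel_size)
}
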