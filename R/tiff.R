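## Minimal baseline TIFF codec (no TIFF package is available in this
## toolchain). Little-endian, uncompressed, single-sample grayscale,
## multi-page. Movies/maps are stored as 64-bit IEEE floats so write->read
## round-trips are bit-identical for R doubles; label volumes as uint16
## (uint32 when labels exceed 65535). The reader is deliberately more
## general than the writer: multiple strips, 8/16/32-bit unsigned and
## 32/64-bit float samples.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

tiff_entry <- function(tag, type, count, value) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == TIFF_TYPE_SHORT) {
    writeBin(as.integer(value), con, size = 2, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  rawConnectionValue(con)
}

#' Write matrices as a multi-page grayscale TIFF
#'
#' @param path output file.
#' @param pages list of numeric matrices (pixels written row-major, one
#'   page per list element).
#' @param sample `"float"` (64-bit IEEE) or `"uint"` (16-bit, widened to
#'   32-bit when values exceed 65535).
#' @return `path`, invisibly.
#' @export
write_tiff_pages <- function(path, pages, sample = c("float", "uint")) {
  sample <- match.arg(sample)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stopf("no pages to write")
  for (p in pages) if (!is.matrix(p)) stopf("every page must be a matrix")
  if (sample == "uint") {
    mx <- max(vapply(pages, max, numeric(1)), 0)
    if (any(vapply(pages, min, numeric(1)) < 0)) stopf("uint pages must be >= 0")
    bits <- if (mx > 65535) 32L else 16L
    fmt <- 1L
  } else {
    bits <- 64L
    fmt <- 3L
  }
  bpp <- bits %/% 8L
  npages <- length(pages)
  data_bytes <- vapply(pages, function(p) length(p) * bpp, numeric(1))
  data_off <- 8 + c(0, cumsum(data_bytes))[seq_len(npages)]
  ifd_size <- 2 + 10 * 12 + 4
  ifd_off <- 8 + sum(data_bytes) + (seq_len(npages) - 1) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")
  for (i in seq_len(npages)) {
    v <- as.vector(t(pages[[i]]))                 # row-major pixel order
    if (sample == "float") writeBin(as.double(v), con, size = 8, endian = "little")
    else writeBin(as.integer(v), con, size = bpp, endian = "little")
  }
  for (i in seq_len(npages)) {
    p <- pages[[i]]
    h <- nrow(p); w <- ncol(p)
    entries <- list(
      tiff_entry(256, TIFF_TYPE_LONG, 1, w),
      tiff_entry(257, TIFF_TYPE_LONG, 1, h),
      tiff_entry(258, TIFF_TYPE_SHORT, 1, bits),
      tiff_entry(259, TIFF_TYPE_SHORT, 1, 1),     # no compression
      tiff_entry(262, TIFF_TYPE_SHORT, 1, 1),     # BlackIsZero
      tiff_entry(273, TIFF_TYPE_LONG, 1, data_off[i]),
      tiff_entry(277, TIFF_TYPE_SHORT, 1, 1),
      tiff_entry(278, TIFF_TYPE_LONG, 1, h),      # single strip
      tiff_entry(279, TIFF_TYPE_LONG, 1, data_bytes[i]),
      tiff_entry(339, TIFF_TYPE_SHORT, 1, fmt))
    writeBin(10L, con, size = 2, endian = "little")
    for (e in entries) writeBin(e, con)
    nxt <- if (i < npages) ifd_off[i + 1] else 0
    writeBin(as.integer(nxt), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports little-endian, uncompressed, single-sample images with 8/16/32
#' bit unsigned or 32/64 bit float samples, in one or more strips.
#'
#' @param path TIFF file.
#' @return List of numeric matrices, one per page.
#' @export
read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  if (rawToChar(raw[1:2]) != "II")
    stopf("only little-endian ('II') TIFF is supported")
  if (u16(2) != 42L) stopf("not a TIFF file: %s", path)
  off <- u32(4)
  pages <- list()
  while (off != 0) {
    nent <- u16(off)
    tags <- list()
    for (k in seq_len(nent)) {
      e <- off + 2 + (k - 1) * 12
      tag <- u16(e); type <- u16(e + 2); cnt <- u32(e + 4)
      size <- c(1, 1, 2, 4, 8)[type]
      inline <- size * cnt <= 4
      val <- if (type == TIFF_TYPE_SHORT) {
        if (inline) vapply(seq_len(cnt) - 1L, function(j) u16(e + 8 + 2 * j), 0L)
        else { vo <- u32(e + 8); vapply(seq_len(cnt) - 1L, function(j) u16(vo + 2 * j), 0L) }
      } else if (type == TIFF_TYPE_LONG) {
        if (inline) u32(e + 8)
        else { vo <- u32(e + 8); vapply(seq_len(cnt) - 1L, function(j) u32(vo + 4 * j), 0L) }
      } else NULL
      if (!is.null(val)) tags[[as.character(tag)]] <- val
    }
    need <- function(tag) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) stopf("TIFF page is missing required tag %d", tag)
      v
    }
    w <- need(256)[1]; h <- need(257)[1]
    if ((tags[["277"]] %||% 1L)[1] != 1L)
      stopf("only single-sample (grayscale) TIFF is supported")
    bits <- (tags[["258"]] %||% 1L)[1]      # some writers repeat this tag value
    if ((tags[["259"]] %||% 1L)[1] != 1L) stopf("compressed TIFF not supported")
    fmt <- (tags[["339"]] %||% 1L)[1]
    offs <- need(273)
    counts <- need(279)
    vals <- unlist(lapply(seq_along(offs), function(s) {
      seg <- raw[(offs[s] + 1):(offs[s] + counts[s])]
      if (fmt == 3L) {
        if (bits == 64) readBin(seg, "double", n = counts[s] / 8, size = 8,
                                endian = "little")
        else if (bits == 32) readBin(seg, "double", n = counts[s] / 4, size = 4,
                                     endian = "little")
        else stopf("unsupported float bit depth %d", bits)
      } else if (fmt == 1L) {
        if (bits == 8) as.integer(seg)
        else if (bits == 16) readBin(seg, "integer", n = counts[s] / 2, size = 2,
                                     signed = FALSE, endian = "little")
        else if (bits == 32) readBin(seg, "integer", n = counts[s] / 4, size = 4,
                                     endian = "little")
        else stopf("unsupported uint bit depth %d", bits)
      } else stopf("unsupported TIFF sample format %d", fmt)
    }))
    if (length(vals) != w * h) stopf("TIFF strip data does not match page size")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, byrow = TRUE)
    off <- u32(off + 2 + nent * 12)
  }
  pages
}
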