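# Minimal multi-page grayscale TIFF codec (uncompressed, little-endian).
#
# No pre-installed R package in this stack reads TIFF, so label/bead volumes
# are serialized with this purpose-built codec. Scope is deliberately narrow:
# 8- or 16-bit unsigned grayscale, no compression, strip-organized. That is
# exactly what segmentation exports and the phantom generator need; anything
# else is rejected loudly rather than guessed at.

TIFF_TAG <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
              photometric = 262L, strip_offsets = 273L, samples = 277L,
              rows_per_strip = 278L, strip_counts = 279L)

#' Read a multi-page grayscale TIFF stack
#'
#' Reads an uncompressed 8- or 16-bit grayscale multi-page TIFF into a 3D
#' integer array indexed `[z, y, x]` (page, row, column). All pages must share
#' one width/height/bit depth.
#'
#' @param path path to a TIFF file
#' @return integer array with dim `c(n_pages, height, width)`
#' @export
read_tiff_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(magic, as.raw(c(0x49, 0x49)))) "little"
            else if (identical(magic, as.raw(c(0x4d, 0x4d)))) "big"
            else stop("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (fortytwo != 42L) stop("bad TIFF magic number in ", path)
  ifd_offset <- readBin(con, "integer", 1, size = 4, endian = endian)

  pages <- list()
  while (ifd_offset != 0) {
    seek(con, ifd_offset)
    n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
      type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
      count <- readBin(con, "integer", 1, size = 4, endian = endian)
      value_raw <- readBin(con, "raw", 4)
      tags[[as.character(tag)]] <- list(type = type, count = count, raw = value_raw)
    }
    ifd_offset <- readBin(con, "integer", 1, size = 4, endian = endian)
    pages[[length(pages) + 1L]] <- tags
  }
  if (!length(pages)) stop("TIFF has no pages: ", path)

  read_tag_values <- function(tags, tag_id, default = NULL) {
    entry <- tags[[as.character(tag_id)]]
    if (is.null(entry)) {
      if (!is.null(default)) return(default)
      stop("required TIFF tag ", tag_id, " missing")
    }
    size <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(entry$type)]
    if (is.na(size)) stop("unsupported TIFF tag type ", entry$type)
    total <- size * entry$count
    signed <- size >= 4  # R cannot read unsigned 32-bit; offsets < 2GB anyway
    if (total <= 4) {
      vals <- readBin(entry$raw, "integer", entry$count, size = size,
                      signed = signed, endian = endian)
    } else {
      off <- readBin(entry$raw, "integer", 1, size = 4, endian = endian)
      seek(con, off)
      vals <- readBin(con, "integer", entry$count, size = size,
                      signed = signed, endian = endian)
    }
    vals
  }

  read_page <- function(tags) {
    w <- read_tag_values(tags, TIFF_TAG["width"])
    h <- read_tag_values(tags, TIFF_TAG["length"])
    bits <- read_tag_values(tags, TIFF_TAG["bits"], default = 1L)[1]
    comp <- read_tag_values(tags, TIFF_TAG["compression"], default = 1L)
    samples <- read_tag_values(tags, TIFF_TAG["samples"], default = 1L)
    if (comp != 1L) stop("only uncompressed TIFF is supported (compression=", comp, ")")
    if (samples != 1L) stop("only single-sample grayscale TIFF is supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF is supported (bits=", bits, ")")
    offsets <- read_tag_values(tags, TIFF_TAG["strip_offsets"])
    counts <- read_tag_values(tags, TIFF_TAG["strip_counts"])
    px <- integer(0)
    for (s in seq_along(offsets)) {
      seek(con, offsets[s])
      n_px <- counts[s] %/% (bits %/% 8L)
      px <- c(px, readBin(con, "integer", n_px, size = bits %/% 8L,
                          signed = FALSE, endian = endian))
    }
    if (length(px) != w * h) stop("TIFF strip data does not match page dimensions")
    list(w = w, h = h, data = px)
  }

  decoded <- lapply(pages, read_page)
  w <- decoded[[1]]$w; h <- decoded[[1]]$h
  if (!all(vapply(decoded, function(p) p$w == w && p$h == h, logical(1))))
    stop("TIFF pages have inconsistent dimensions")
  arr <- array(0L, dim = c(length(decoded), h, w))
  for (k in seq_along(decoded)) {
    # pixel stream is row-major (row = y, col = x)
    arr[k, , ] <- matrix(decoded[[k]]$data, nrow = h, ncol = w, byrow = TRUE)
  }
  arr
}

#' Write a multi-page grayscale TIFF stack
#'
#' Writes an integer array indexed `[z, y, x]` as an uncompressed
#' little-endian grayscale multi-page TIFF, one strip per page.
#'
#' @param x integer array with dim `c(n_pages, height, width)`; values must
#'   fit the requested bit depth
#' @param path output path
#' @param bits 8 or 16 (default 16)
#' @return `path`, invisibly
#' @export
write_tiff_stack <- function(x, path, bits = 16L) {
  if (length(dim(x)) != 3) stop("x must be a 3D array [z, y, x]")
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  maxval <- 2^bits - 1
  if (any(x < 0) || any(x > maxval)) stop("values out of range for ", bits, "-bit TIFF")
  nz <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  bytes_per_px <- bits %/% 8L
  strip_bytes <- w * h * bytes_per_px
  n_tags <- 9L
  ifd_bytes <- 2L + n_tags * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49)), con)                      # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")            # first IFD at byte 8

  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) { w2(tag); w2(type); w4(count); w4(value) }

  offset <- 8L
  for (k in seq_len(nz)) {
    data_offset <- offset + ifd_bytes
    next_ifd <- if (k < nz) data_offset + strip_bytes else 0L
    w2(n_tags)
    entry(TIFF_TAG["width"], 3L, 1L, w)
    entry(TIFF_TAG["length"], 3L, 1L, h)
    entry(TIFF_TAG["bits"], 3L, 1L, bits)
    entry(TIFF_TAG["compression"], 3L, 1L, 1L)
    entry(TIFF_TAG["photometric"], 3L, 1L, 1L)              # black-is-zero
    entry(TIFF_TAG["strip_offsets"], 4L, 1L, data_offset)
    entry(TIFF_TAG["samples"], 3L, 1L, 1L)
    entry(TIFF_TAG["rows_per_strip"], 3L, 1L, h)
    entry(TIFF_TAG["strip_counts"], 4L, 1L, strip_bytes)
    w4(next_ifd)
    page <- t(matrix(x[k, , ], nrow = h, ncol = w))         # to row-major stream
    writeBin(as.integer(page), con, size = bytes_per_px, endian = "little")
    offset <- data_offset + strip_bytes
  }
  invisible(path)
}
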