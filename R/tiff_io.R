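## Minimal baseline TIFF reader/writer (uncompressed, single-sample grayscale,
## little-endian, multi-page). The analysis environment ships no R TIFF
## package, and field images only need lossless grayscale round-trips, so a
## small self-contained implementation is used. Validated against an external
## reference reader in the test suite.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               RowsPerStrip = 278L, StripByteCounts = 279L, SampleFormat = 339L)

#' Write grayscale images as a multi-page TIFF
#'
#' Writes one page per matrix: uncompressed, little-endian, single channel.
#' `float32` preserves intensities exactly as single precision; `uint16`
#' rounds to integers in `[0, 65535]`.
#'
#' @param img A numeric matrix or a list of numeric matrices (pages).
#' @param path Output file path.
#' @param dtype `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @seealso [read_tiff()]
#' @export
write_tiff <- function(img, path, dtype = c("float32", "uint16")) {
  dtype <- match.arg(dtype)
  pages <- if (is.matrix(img)) list(img) else img
  stopifnot(length(pages) >= 1L, all(vapply(pages, is.matrix, logical(1))))
  bps <- if (dtype == "float32") 32L else 16L
  fmt <- if (dtype == "float32") 3L else 1L   # IEEE float / unsigned int
  bytes_px <- bps / 8L
  n <- length(pages)
  ifd_size <- 2L + 9L * 12L + 4L
  # layout: header | page data ... | IFDs
  data_off <- integer(n)
  off <- 8L
  for (i in seq_len(n)) {
    data_off[i] <- off
    off <- off + length(pages[[i]]) * bytes_px
  }
  ifd_off <- off + (seq_len(n) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w2(42L)
  w4(ifd_off[1])
  for (i in seq_len(n)) {
    v <- as.vector(t(pages[[i]]))            # row-major pixel order
    if (dtype == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- as.integer(pmax(0, pmin(65535, round(v))))
      v[v > 32767L] <- v[v > 32767L] - 65536L  # two's-complement for writeBin
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  for (i in seq_len(n)) {
    m <- pages[[i]]
    entry <- function(tag, type, count, value) {
      w2(tag); w2(type); w4(count)
      if (type == 3L) { w2(value); w2(0L) } else w4(value)
    }
    w2(9L)  # entry count
    entry(TIFF_TAGS[["ImageWidth"]], 4L, 1L, ncol(m))
    entry(TIFF_TAGS[["ImageLength"]], 4L, 1L, nrow(m))
    entry(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, bps)
    entry(TIFF_TAGS[["Compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off[i])
    entry(TIFF_TAGS[["RowsPerStrip"]], 4L, 1L, nrow(m))
    entry(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, length(m) * bytes_px)
    entry(TIFF_TAGS[["SampleFormat"]], 3L, 1L, fmt)
    w4(if (i < n) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF
#'
#' Supports the subset this package writes (plus common reference-writer
#' output): uncompressed single-sample grayscale pages, 8/16/32-bit unsigned
#' integer or 32-bit float, little- or big-endian, any strip layout.
#'
#' @param path TIFF file path.
#' @return A list of numeric matrices, one per page.
#' @seealso [write_tiff()]
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path)
  rd <- function(off, size, n, what = "integer", signed = TRUE)
    readBin(raw[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed || size > 2)
  if (rd(2, 2, 1) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd(4, 4, 1)
  pages <- list()
  while (ifd_off > 0) {
    n_entries <- rd(ifd_off, 2, 1)
    tags <- list()
    for (j in seq_len(n_entries)) {
      e <- ifd_off + 2 + (j - 1) * 12
      tag <- rd(e, 2, 1, signed = FALSE)
      type <- rd(e + 2, 2, 1)
      count <- rd(e + 4, 4, 1)
      tsize <- c(`1` = 1L, `3` = 2L, `4` = 4L)[as.character(type)]
      if (is.na(tsize)) { next }  # skip rational/ascii tags
      voff <- if (tsize * count <= 4) e + 8 else rd(e + 8, 4, 1)
      tags[[as.character(tag)]] <- rd(voff, tsize, count, signed = FALSE)
    }
    g <- function(tag, default = NULL) tags[[as.character(TIFF_TAGS[[tag]])]] %||% default
    wd <- g("ImageWidth"); ht <- g("ImageLength")
    bps <- g("BitsPerSample", 8L)[1]
    if ((g("Compression", 1L)) != 1L) stop("compressed TIFF not supported")
    fmt <- g("SampleFormat", 1L)[1]
    offs <- g("StripOffsets"); cnts <- g("StripByteCounts")
    buf <- unlist(lapply(seq_along(offs), function(k)
      raw[(offs[k] + 1):(offs[k] + cnts[k])]), use.names = FALSE)
    npx <- wd * ht
    v <- if (fmt == 3L && bps == 32L) {
      readBin(buf, "numeric", n = npx, size = 4, endian = endian)
    } else if (bps == 8L) {
      as.numeric(readBin(buf, "integer", n = npx, size = 1, endian = endian,
                         signed = FALSE))
    } else if (bps == 16L) {
      as.numeric(readBin(buf, "integer", n = npx, size = 2, endian = endian,
                         signed = FALSE))
    } else if (bps == 32L) {
      as.numeric(readBin(buf, "integer", n = npx, size = 4, endian = endian))
    } else stop("unsupported bit depth: ", bps)
    pages[[length(pages) + 1L]] <- matrix(v, nrow = ht, ncol = wd, byrow = TRUE)
    nxt_off <- ifd_off + 2 + n_entries * 12
    ifd_off <- rd(nxt_off, 4, 1)
  }
  pages
}
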