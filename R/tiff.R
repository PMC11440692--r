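# Minimal baseline-TIFF codec for single-channel integer label images.
#
# No TIFF reader is available in the dependency set, and label masks are a
# first-class exchange format here, so the package carries a deliberately
# small codec: uncompressed, single-sample, 8- or 16-bit grayscale, either
# byte order on read; writes are always little-endian uint16, single strip.
# This is the subset produced by common scientific writers (e.g. tifffile
# with compression disabled) and is round-trip exact.

.tif_read_uint <- function(raw, pos, size, n, endian) {
  v <- readBin(raw[pos:(pos + size * n - 1L)], "integer", n = n, size = size,
               signed = size >= 4L, endian = endian)
  if (size == 4L && any(v < 0)) stop("TIFF offsets >= 2^31 are unsupported", call. = FALSE)
  v
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  bom <- rawToChar(raw[1:2])
  endian <- if (bom == "II") "little" else if (bom == "MM") "big" else
    stop("not a TIFF file: ", path, call. = FALSE)
  if (.tif_read_uint(raw, 3L, 2L, 1L, endian) != 42L) {
    stop("not a TIFF file: ", path, call. = FALSE)
  }
  ifd <- .tif_read_uint(raw, 5L, 4L, 1L, endian)
  n_entries <- .tif_read_uint(raw, ifd + 1L, 2L, 1L, endian)
  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd + 3L + (k - 1L) * 12L
    tag <- .tif_read_uint(raw, e, 2L, 1L, endian)
    typ <- .tif_read_uint(raw, e + 2L, 2L, 1L, endian)
    cnt <- .tif_read_uint(raw, e + 4L, 4L, 1L, endian)
    if (typ > 5L || typ < 1L) next
    sz <- type_size[typ]
    if (typ == 5L) next  # rationals (resolution tags) are irrelevant here
    vpos <- if (sz * cnt <= 4L) e + 8L else .tif_read_uint(raw, e + 8L, 4L, 1L, endian) + 1L
    tags[[as.character(tag)]] <- .tif_read_uint(raw, vpos, sz, cnt, endian)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, call. = FALSE)
      default
    } else v
  }
  width <- need(256L); height <- need(257L)
  bits <- need(258L, 1L)
  if (need(259L, 1L) != 1L) stop("compressed TIFF is unsupported", call. = FALSE)
  if (need(277L, 1L) != 1L) stop("multi-sample TIFF is unsupported", call. = FALSE)
  if (!bits %in% c(8L, 16L)) stop("only 8- or 16-bit TIFF is supported", call. = FALSE)
  offsets <- need(273L); counts <- need(279L, width * height * bits / 8L)
  data <- raw(0)
  for (k in seq_along(offsets)) {
    data <- c(data, raw[(offsets[k] + 1L):(offsets[k] + counts[k])])
  }
  vals <- readBin(data, "integer", n = width * height, size = bits / 8L,
                  signed = FALSE, endian = endian)
  matrix(vals, nrow = height, ncol = width, byrow = TRUE)
}

write_tiff_gray <- function(m, path) {
  m <- as.matrix(m)
  if (any(m < 0L | m > 65535L)) stop("label values must lie in [0, 65535]", call. = FALSE)
  storage.mode(m) <- "integer"
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeBin(charToRaw("II"), con); wr(42L, 2L)
  nbytes <- 2L * w * h
  wr(8L + nbytes, 4L)               # IFD sits right after the pixel data
  wr(as.vector(t(m)), 2L)           # row-major strip at offset 8
  entry <- function(tag, typ, cnt, val) {
    wr(tag, 2L); wr(typ, 2L); wr(cnt, 4L)
    if (typ == 3L) { wr(val, 2L); wr(0L, 2L) } else wr(val, 4L)
  }
  wr(10L, 2L)                       # entry count
  entry(256L, 4L, 1L, w)            # ImageWidth
  entry(257L, 4L, 1L, h)            # ImageLength
  entry(258L, 3L, 1L, 16L)          # BitsPerSample
  entry(259L, 3L, 1L, 1L)           # Compression = none
  entry(262L, 3L, 1L, 1L)           # Photometric = BlackIsZero
  entry(273L, 4L, 1L, 8L)           # StripOffsets
  entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
  entry(278L, 4L, 1L, h)            # RowsPerStrip
  entry(279L, 4L, 1L, nbytes)       # StripByteCounts
  entry(339L, 3L, 1L, 1L)           # SampleFormat = unsigned
  wr(0L, 4L)                        # no next IFD
  invisible(path)
}
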