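# Minimal baseline-TIFF reader/writer: uncompressed, single image, bilevel
# (1-bit), 8-bit grayscale, or 8-bit RGB (converted to luminance on read).
# Deliberately small: the flatbed protocol produces plain uncompressed
# black-and-white TIFFs, and no TIFF package is assumed at run time.

TAG_WIDTH <- 256L; TAG_HEIGHT <- 257L; TAG_BITS <- 258L; TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L; TAG_STRIP_OFFSETS <- 273L; TAG_SPP <- 277L
TAG_ROWS_PER_STRIP <- 278L; TAG_STRIP_BYTES <- 279L
TAG_XRES <- 282L; TAG_YRES <- 283L; TAG_RES_UNIT <- 296L

rd_int <- function(r, pos, size, endian) {
  v <- readBin(r[pos:(pos + size - 1L)], "integer", n = 1L, size = size,
               signed = size == 4L, endian = endian)
  if (v < 0) stop("TIFF value out of supported range (>= 2^31)")
  v
}

tiff_read_raw <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 8) stop("cannot read TIFF file: ", path)
  r <- readBin(path, "raw", n = n)
  endian <- if (r[1] == as.raw(0x49) && r[2] == as.raw(0x49)) "little"
            else if (r[1] == as.raw(0x4d) && r[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  if (rd_int(r, 3L, 2L, endian) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd <- rd_int(r, 5L, 4L, endian)
  nent <- rd_int(r, ifd + 1L, 2L, endian)
  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  tags <- list()
  for (k in seq_len(nent)) {
    at <- ifd + 3L + (k - 1L) * 12L
    tag <- rd_int(r, at, 2L, endian)
    typ <- rd_int(r, at + 2L, 2L, endian)
    cnt <- rd_int(r, at + 4L, 4L, endian)
    if (typ > 5L) next
    sz <- type_size[typ] * cnt
    vpos <- if (sz <= 4L) at + 8L else rd_int(r, at + 8L, 4L, endian) + 1L
    vals <- switch(as.character(typ),
      "1" = , "2" = as.integer(r[vpos:(vpos + cnt - 1L)]),
      "3" = vapply(seq_len(cnt), function(i) rd_int(r, vpos + 2L * (i - 1L), 2L, endian), 0L),
      "4" = vapply(seq_len(cnt), function(i) rd_int(r, vpos + 4L * (i - 1L), 4L, endian), 0L),
      "5" = vapply(seq_len(cnt), function(i) {
              num <- rd_int(r, vpos + 8L * (i - 1L), 4L, endian)
              den <- rd_int(r, vpos + 8L * (i - 1L) + 4L, 4L, endian)
              if (den == 0) NA_real_ else num / den
            }, 0)
    )
    tags[[as.character(tag)]] <- vals
  }
  list(raw = r, tags = tags, endian = endian)
}

tag_or <- function(tags, tag, default) {
  v <- tags[[as.character(tag)]]
  if (is.null(v)) default else v
}

# Returns list(pixels = integer matrix (rows = y), max_value, dpi or NA).
read_tiff_gray <- function(path) {
  tf <- tiff_read_raw(path)
  tags <- tf$tags
  w <- tag_or(tags, TAG_WIDTH, NULL); h <- tag_or(tags, TAG_HEIGHT, NULL)
  if (is.null(w) || is.null(h)) stop("TIFF missing image dimensions: ", path)
  comp <- tag_or(tags, TAG_COMPRESSION, 1L)
  if (comp != 1L) stop("only uncompressed TIFF is supported (compression tag ",
                       comp, "): ", path)
  bits <- tag_or(tags, TAG_BITS, 1L)
  spp <- tag_or(tags, TAG_SPP, 1L)
  if (!(spp %in% c(1L, 3L))) stop("unsupported samples per pixel: ", spp)
  if (spp == 3L && !all(bits == 8L)) stop("RGB TIFF must be 8 bits per sample")
  if (spp == 1L && !(bits[1] %in% c(1L, 8L))) stop("unsupported bit depth: ", bits[1])
  offs <- tag_or(tags, TAG_STRIP_OFFSETS, NULL)
  cnts <- tag_or(tags, TAG_STRIP_BYTES, NULL)
  if (is.null(offs) || is.null(cnts)) stop("TIFF missing strip layout: ", path)
  data <- do.call(c, lapply(seq_along(offs), function(i)
    tf$raw[(offs[i] + 1L):(offs[i] + cnts[i])]))
  if (spp == 1L && bits[1] == 1L) {
    rowbytes <- (w + 7L) %/% 8L
    bm <- matrix(as.integer(rawToBits(data[seq_len(rowbytes * h)])), nrow = 8L)
    bm <- bm[8L:1L, , drop = FALSE]  # TIFF packs MSB-first
    px <- matrix(0L, h, w)
    allbits <- matrix(as.integer(bm), nrow = rowbytes * 8L)  # column = image row
    px[] <- t(allbits[seq_len(w), , drop = FALSE])
    maxv <- 1L
  } else if (spp == 1L) {
    px <- matrix(as.integer(data[seq_len(w * h)]), nrow = h, byrow = TRUE)
    maxv <- 255L
  } else {
    v <- as.integer(data[seq_len(3L * w * h)])
    lum <- as.integer(round(0.299 * v[c(TRUE, FALSE, FALSE)] +
                            0.587 * v[c(FALSE, TRUE, FALSE)] +
                            0.114 * v[c(FALSE, FALSE, TRUE)]))
    px <- matrix(lum, nrow = h, byrow = TRUE)
    maxv <- 255L
  }
  photo <- tag_or(tags, TAG_PHOTOMETRIC, if (spp == 3L) 2L else 1L)
  if (spp == 1L && photo == 0L) px <- maxv - px  # WhiteIsZero -> intensity
  res <- tag_or(tags, TAG_XRES, NA_real_)[1]
  unit <- tag_or(tags, TAG_RES_UNIT, 2L)[1]
  dpi <- if (is.na(res) || unit == 1L) NA_real_
         else if (unit == 3L) res * 2.54 else res
  list(pixels = px, max_value = maxv, dpi = dpi)
}

w16 <- function(con, v) writeBin(as.integer(v), con, size = 2L, endian = "little")
w32 <- function(con, v) writeBin(as.integer(v), con, size = 4L, endian = "little")

# pixels: integer matrix; bilevel written as 1-bit when max_value == 1.
write_tiff_gray <- function(path, pixels, dpi, max_value = 255L) {
  h <- nrow(pixels); w <- ncol(pixels)
  onebit <- max_value == 1L
  if (onebit) {
    rowbytes <- (w + 7L) %/% 8L
    padded <- matrix(0L, nrow = h, ncol = rowbytes * 8L)
    padded[, seq_len(w)] <- pixels
    bits <- as.integer(t(padded))                 # row-major pixel stream
    bm <- matrix(bits, nrow = 8L)[8L:1L, , drop = FALSE]  # MSB-first
    data <- packBits(as.integer(bm) != 0L, type = "raw")
  } else {
    data <- as.raw(as.integer(t(pixels)))
  }
  nbytes <- length(data)
  # layout: header(8) | pixel data | XRes(8) | YRes(8) | IFD
  data_off <- 8L
  xres_off <- data_off + nbytes
  yres_off <- xres_off + 8L
  ifd_off <- yres_off + 8L
  dpi_num <- as.integer(round(dpi * 100)); dpi_den <- 100L
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("II"), con); w16(con, 42L); w32(con, ifd_off)
  writeBin(data, con)
  w32(con, dpi_num); w32(con, dpi_den)
  w32(con, dpi_num); w32(con, dpi_den)
  entry <- function(tag, typ, cnt, val) {
    w16(con, tag); w16(con, typ); w32(con, cnt)
    if (typ == 3L) { w16(con, val); w16(con, 0L) } else w32(con, val)
  }
  w16(con, 12L)
  entry(TAG_WIDTH, 4L, 1L, w)
  entry(TAG_HEIGHT, 4L, 1L, h)
  entry(TAG_BITS, 3L, 1L, if (onebit) 1L else 8L)
  entry(TAG_COMPRESSION, 3L, 1L, 1L)
  entry(TAG_PHOTOMETRIC, 3L, 1L, 1L)  # BlackIsZero
  entry(TAG_STRIP_OFFSETS, 4L, 1L, data_off)
  entry(TAG_SPP, 3L, 1L, 1L)
  entry(TAG_ROWS_PER_STRIP, 4L, 1L, h)
  entry(TAG_STRIP_BYTES, 4L, 1L, nbytes)
  entry(TAG_XRES, 5L, 1L, xres_off)
  entry(TAG_YRES, 5L, 1L, yres_off)
  entry(TAG_RES_UNIT, 3L, 1L, 2L)  # inch
  w32(con, 0L)  # no further IFD
  invisible(path)
}
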