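#' Read a gel image from PNG
#'
#' Decodes an 8- or 16-bit PNG into a numeric matrix in the original stored
#' units: 8-bit images yield values in 0..255, 16-bit images values in
#' 0..65535. No rescaling to a common range is performed; per-image intensity
#' scale is handled later by [normalize_stack()], keeping raw units
#' inspectable. Color images are accepted and converted to grayscale by the
#' mean of the color channels (alpha, if present, is dropped); the conversion
#' is logged.
#'
#' @param path path to a PNG file.
#' @return numeric matrix (`H x W`) of intensities in original units.
#' @export
read_gel_png <- function(path) {
  if (!file.exists(path)) {
    gc_stop(sprintf("image file not found: %s", path), "gelcorr_io_error")
  }
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 4L || nc == 2L) img <- img[, , -nc, drop = FALSE]  # drop alpha
    gc_info(sprintf(
      "converting %d-channel image to grayscale by channel mean: %s",
      dim(img)[3], path
    ))
    img <- apply(img, c(1, 2), mean)
  }
  out <- round(img * (2^depth - 1))
  matrix(as.vector(out), nrow(out), ncol(out))
}

#' Write a gel image to PNG
#'
#' Writes a numeric matrix as an 8- or 16-bit grayscale PNG. Values are
#' rounded to integers and must lie within the representable range
#' (0..255 or 0..65535). 16-bit output preserves the dynamic range of
#' synthetic and camera-export images; the stored sample values round-trip
#' exactly through [read_gel_png()].
#'
#' @param image numeric matrix of intensities.
#' @param path output path.
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gel_png <- function(image, path, bits = 16L) {
  if (!is.matrix(image)) gc_stop("image must be a 2D matrix", "gelcorr_io_error")
  if (!bits %in% c(8L, 16L)) gc_stop("bits must be 8 or 16", "gelcorr_io_error")
  maxv <- 2^bits - 1
  v <- round(image)
  if (anyNA(v) || min(v) < 0 || max(v) > maxv) {
    gc_stop(sprintf("image values must be finite and within [0, %d] for %d-bit PNG",
                    maxv, bits), "gelcorr_io_error")
  }
  if (bits == 8L) {
    png::writePNG(v / 255, path)
  } else {
    write_png16_gray(v, path)
  }
  invisible(path)
}

## ---- minimal 16-bit grayscale PNG encoder -------------------------------
## The zlib stream PNG requires for IDAT is produced by memCompress(), which
## emits RFC 1950 (zlib) framing; chunk CRC-32s are computed here. Output is
## verified against png::readPNG in the test suite.

xor32 <- function(a, b) {
  # bitwise xor of two 32-bit unsigned values stored as doubles
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
    bitwXor(as.integer(al), as.integer(bl))
}

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (k in 0:255) {
        c <- as.numeric(k)
        for (j in 1:8) {
          c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
        }
        t[k + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  b <- as.integer(bytes)
  crc <- 4294967295
  for (i in seq_along(b)) {
    idx <- bitwXor(as.integer(crc %% 256), b[i])
    crc <- xor32(crc %/% 256, tab[idx + 1])
  }
  xor32(crc, 4294967295)
}

uint_be <- function(x, width) {
  out <- integer(width)
  for (i in width:1) {
    out[i] <- as.integer(x %% 256)
    x <- x %/% 256
  }
  as.raw(out)
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint_be(length(data), 4), body, uint_be(crc32(body), 4))
}

write_png16_gray <- function(v, path) {
  h <- nrow(v); w <- ncol(v)
  m <- t(v)                                   # columns of m = image rows
  hi <- m %/% 256; lo <- m %% 256
  bytes <- matrix(0L, 2L * w + 1L, h)         # leading 0 = per-row filter byte
  bytes[seq(2L, 2L * w, 2L) , ] <- hi
  bytes[seq(3L, 2L * w + 1L, 2L), ] <- lo
  raw_scanlines <- as.raw(as.vector(bytes))
  zlib <- memCompress(raw_scanlines, type = "gzip")
  if (zlib[1] != as.raw(0x78)) {
    gc_stop("memCompress did not produce a zlib stream", "gelcorr_io_error")
  }
  ihdr <- c(uint_be(w, 4), uint_be(h, 4),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))   # depth 16, gray, deflate, filt0, no interlace
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path, useBytes = TRUE)
  invisible(path)
}
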