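# 16-bit grayscale PNG output. The png package reads 16-bit files but only
# writes 8-bit, so the writer is implemented here (IHDR/IDAT/IEND chunks,
# zlib deflate via memCompress, table-driven CRC-32).

# bitwShiftR is a logical shift on the 32-bit pattern, which is exactly what
# the unsigned CRC recurrence needs; -306674912L is the 0xEDB88320 polynomial.
.crc32_table <- local({
  vapply(0:255, function(n) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) == 1L)
        bitwXor(-306674912L, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    c
  }, integer(1))
})

.crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L) + 1L
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc32_table[idx])
  }
  bitwXor(crc, -1L)
}

.u32_raw <- function(x) {
  # unsigned 32-bit big-endian from a (possibly negative) int32 bit pattern
  x <- as.numeric(x)
  if (x < 0) x <- x + 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32_raw(length(data)), body, .u32_raw(.crc32(body)))
}

#' Write a slice image as 16-bit grayscale PNG
#'
#' Intensities are scaled linearly so that `max_intensity` maps to 65535;
#' the scale and pixel spacing are not stored in the PNG, so reading it back
#' requires a spacing override (see [read_image()]).
#'
#' @param image a `slice_image`.
#' @param path output path.
#' @param max_intensity intensity mapped to full scale; defaults to the image
#'   maximum.
#' @return `path`, invisibly.
#' @export
write_png16 <- function(image, path, max_intensity = NULL) {
  px <- image$pixels
  max_intensity <- max_intensity %||% max(px)
  if (max_intensity <= 0) max_intensity <- 1
  q <- round(pmin(pmax(px / max_intensity, 0), 1) * 65535)
  nr <- nrow(q); nc <- ncol(q)
  ihdr <- c(.u32_raw(nc), .u32_raw(nr),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, grayscale
  # scanlines: filter byte 0 + big-endian uint16 pixels, row-major
  m <- t(q)  # columns of m are image rows
  hi <- as.raw(m %/% 256); lo <- as.raw(m %% 256)
  scan <- raw(nr * (1L + 2L * nc))
  rowlen <- 1L + 2L * nc
  for (r in seq_len(nr)) {
    off <- (r - 1L) * rowlen
    scan[off + 1L] <- as.raw(0L)
    scan[off + 1L + seq(1L, 2L * nc, by = 2L)] <- hi[((r - 1L) * nc + 1L):(r * nc)]
    scan[off + 1L + seq(2L, 2L * nc, by = 2L)] <- lo[((r - 1L) * nc + 1L):(r * nc)]
  }
  idat <- memCompress(scan, type = "gzip")  # R emits a zlib (RFC 1950) stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .png_chunk("IHDR", ihdr),
           .png_chunk("IDAT", idat),
           .png_chunk("IEND", raw(0)))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_io(sprintf("cannot open '%s' for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
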