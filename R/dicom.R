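# Minimal read-only DICOM support: single-frame grayscale images in explicit
# VR little endian (the common export encoding). Enough header is parsed to
# recover the pixel grid and spacing; everything else is ignored. Multi-frame
# files and compressed transfer syntaxes are rejected with a clear error.

.dcm_u16 <- function(b, off) {
  as.integer(b[off + 1]) + 256L * as.integer(b[off + 2])
}
.dcm_u32 <- function(b, off) {
  as.numeric(b[off + 1]) + 256 * as.numeric(b[off + 2]) +
    65536 * as.numeric(b[off + 3]) + 16777216 * as.numeric(b[off + 4])
}

#' Read a single-frame DICOM image
#'
#' Supports uncompressed explicit VR little endian grayscale objects; pixel
#' spacing is taken from Pixel Spacing (0028,0030) when present, otherwise a
#' `spacing` override is required. Multi-frame objects are rejected.
#'
#' @param path DICOM file.
#' @param spacing optional mm-per-pixel override `(x, y)`.
#' @param plane orientation label to attach.
#' @return a `slice_image`.
#' @export
read_dicom <- function(path, spacing = NULL, plane = "coronal") {
  if (!file.exists(path)) stop_io(sprintf("'%s' not found", path))
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop_format(sprintf("'%s' lacks the DICM file marker", path))
  off <- 132L
  rows <- cols <- NULL
  bits <- 16L; signed <- FALSE; frames <- 1L
  px_spacing <- NULL
  pixel_data <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (off + 8L <= length(b)) {
    group <- .dcm_u16(b, off); elem <- .dcm_u16(b, off + 2L)
    vr <- rawToChar(b[(off + 5L):(off + 6L)])
    if (grepl("^[A-Z]{2}$", vr)) {
      if (vr %in% long_vrs) {
        len <- .dcm_u32(b, off + 8L); hdr <- 12L
      } else {
        len <- .dcm_u16(b, off + 6L); hdr <- 8L
      }
    } else {
      # implicit VR fallback
      len <- .dcm_u32(b, off + 4L); hdr <- 8L; vr <- ""
    }
    if (len == 4294967295) stop_format(
      "encapsulated (compressed) DICOM pixel data is not supported")
    val_off <- off + hdr
    if (group == 0x0028) {
      val_str <- function() trimws(rawToChar(b[(val_off + 1L):(val_off + len)]))
      if (elem == 0x0010) rows <- .dcm_u16(b, val_off)
      if (elem == 0x0011) cols <- .dcm_u16(b, val_off)
      if (elem == 0x0100) bits <- .dcm_u16(b, val_off)
      if (elem == 0x0103) signed <- .dcm_u16(b, val_off) == 1L
      if (elem == 0x0008) frames <- as.integer(val_str())
      if (elem == 0x0030)
        px_spacing <- as.numeric(strsplit(val_str(), "\\\\")[[1]])
    }
    if (group == 0x7FE0 && elem == 0x0010) {
      pixel_data <- b[(val_off + 1L):(val_off + len)]
      break
    }
    off <- val_off + len
  }
  if (is.null(rows) || is.null(cols) || is.null(pixel_data))
    stop_format(sprintf("'%s': required DICOM elements missing", path))
  if (frames > 1L)
    stop_format("multi-frame DICOM series are not supported; export single-frame images")
  size <- bits %/% 8L
  vals <- readBin(pixel_data, "integer", rows * cols, size = size,
                  signed = if (size == 2L) signed else TRUE,
                  endian = "little")
  if (size == 2L && !signed) vals <- ifelse(vals < 0, vals + 65536L, vals)
  px <- matrix(as.numeric(vals), rows, cols, byrow = TRUE)
  sp <- spacing %||% rev(px_spacing)  # DICOM stores (row, col) spacing
  if (is.null(sp))
    stop_format("DICOM file has no Pixel Spacing; supply a spacing override")
  slice_image(px, spacing_xy = rep_len(sp, 2L), plane = plane,
              meta = list(source = path, format = "dicom"))
}
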