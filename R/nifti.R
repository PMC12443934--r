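# Minimal NIfTI-1 I/O for 2D magnitude slices. Only the fields this package
# needs are honoured: dim, datatype, bitpix, pixdim, vox_offset, scl_slope/
# scl_inter, magic. Written files are single-file (.nii), float64, "n+1".

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Write a slice image as NIfTI-1
#'
#' Writes a single-file uncompressed `.nii` (float64, magic `n+1`) with the
#' pixel spacing in `pixdim` and the slice thickness as the third pixdim.
#'
#' @param image a `slice_image`.
#' @param path output path (conventionally ending in `.nii`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(image, path) {
  px <- image$pixels
  nx <- ncol(px); ny <- nrow(px)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_io(sprintf("cannot open '%s' for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wc <- function(s, len) {
    r <- charToRaw(s)
    writeBin(c(r, raw(len - length(r))), con)
  }
  thick <- image$meta$sequence$slice_thickness %||% 1
  wi(348L, 4L)                                   # sizeof_hdr
  wc("", 10L); wc("", 18L)                       # data_type, db_name
  wi(0L, 4L); wi(0L, 2L); wc("r", 1L); wc("", 1L)  # extents..dim_info
  wi(c(2L, nx, ny, 1L, 1L, 1L, 1L, 1L), 2L)      # dim
  wf(c(0, 0, 0)); wi(0L, 2L)                     # intent_p*, intent_code
  wi(64L, 2L); wi(64L, 2L); wi(0L, 2L)           # datatype float64, bitpix, slice_start
  wf(c(1, image$spacing_xy[1], image$spacing_xy[2], thick, 0, 0, 0, 0))
  wf(352); wf(1); wf(0)                          # vox_offset, scl_slope/inter
  wi(0L, 2L); wc("", 1L)                         # slice_end, slice_code
  writeBin(as.raw(2L), con)                      # xyzt_units = mm
  wf(c(0, 0, 0, 0))                              # cal_max..toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  wc(sprintf("phantomqa %s slice", image$plane), 80L)
  wc("", 24L)                                    # aux_file
  wi(c(0L, 1L), 2L)                              # qform_code, sform_code=1
  wf(c(0, 0, 0))                                 # quatern b, c, d
  wf(c(image$origin_world[1], image$origin_world[2], 0))  # qoffset
  wf(c(image$spacing_xy[1], 0, 0, image$origin_world[1]))  # srow_x
  wf(c(0, image$spacing_xy[2], 0, image$origin_world[2]))  # srow_y
  wf(c(0, 0, thick, 0))                          # srow_z
  wc("", 16L)
  wc("n+1", 4L)                                  # magic
  writeBin(raw(4L), con)                         # no extensions
  # x varies fastest in NIfTI; our matrix is [row = y, col = x].
  # float64 keeps the round trip bit-exact.
  writeBin(as.numeric(t(px)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file as a slice image
#'
#' Accepts 2D or single-slice 3D single-file NIfTI-1; pixel spacing is taken
#' from `pixdim`, the in-plane origin from `qoffset`/`srow` when a form code
#' is set.
#'
#' @param path `.nii` file.
#' @param plane orientation label to attach (the minimal header does not
#'   encode it).
#' @return a `slice_image`.
#' @export
read_nifti <- function(path, plane = "coronal") {
  if (!file.exists(path)) stop_io(sprintf("'%s' not found", path))
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz_big <- .swap_int32(sz)
    if (sz_big != 348L) stop_format(sprintf("'%s' is not NIfTI-1", path))
    endian <- "big"
  }
  rd_i <- function(n, size) readBin(con, "integer", n, size = size,
                                    endian = endian)
  rd_f <- function(n, size = 4L) readBin(con, "double", n, size = size,
                                         endian = endian)
  invisible(readBin(con, "raw", 36L))            # skip to dim
  dim <- rd_i(8L, 2L)
  invisible(rd_f(3L)); invisible(rd_i(1L, 2L))   # intent
  datatype <- rd_i(1L, 2L)
  invisible(rd_i(2L, 2L))                        # bitpix, slice_start
  pixdim <- rd_f(8L)
  vox_offset <- rd_f(1L)
  scl_slope <- rd_f(1L); scl_inter <- rd_f(1L)
  seek(con, 252L)                                # jump to qform_code
  qform <- rd_i(1L, 2L); sform <- rd_i(1L, 2L)
  invisible(rd_f(3L))                            # quatern
  qoffset <- rd_f(3L)
  srow <- matrix(rd_f(12L), 3, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 16L))
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop_format(sprintf("'%s': unrecognised NIfTI magic '%s'", path, magic))

  ndim <- dim[1]
  nx <- dim[2]; ny <- dim[3]
  nz <- if (ndim >= 3L) dim[4] else 1L
  if (nz > 1L)
    stop_format("multi-slice NIfTI volumes are not supported; supply a 2D or single-slice file")
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt))
    stop_format(sprintf("unsupported NIfTI datatype code %d", datatype))
  seek(con, as.integer(vox_offset))
  n <- as.integer(nx) * as.integer(ny)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop_format("truncated NIfTI pixel data")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  px <- t(matrix(as.numeric(vals), nx, ny))      # back to [row = y, col = x]
  spacing <- c(pixdim[2], pixdim[3])
  origin <- if (sform > 0L) c(srow[1, 4], srow[2, 4])
            else if (qform > 0L) qoffset[1:2] else NULL
  slice_image(px, spacing_xy = spacing, origin_world = origin, plane = plane,
              meta = list(source = path, format = "nifti"))
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}
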