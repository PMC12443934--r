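# Shared fixtures, built in code and cached per test run so expensive renders
# happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  .fixture_cache[[key]]
}

default_row_geometry <- function(...) {
  build_default_phantom("flat", "cor_sag", c("oil", "cu1", "cu2", "cu3"),
                        spacing = 24, ...)
}

noise_free_t1w <- function() cached("t1w0", {
  render_slice(default_row_geometry(), sequence_preset("t1w_coronal"))
})

noise_free_t2w <- function() cached("t2w0", {
  render_slice(default_row_geometry(), sequence_preset("t2w_coronal"))
})

# a tiny synthetic single-frame DICOM (explicit VR little endian), built per
# the standard's encoding rules so the reader is tested against independent
# bytes, not its own writer
make_test_dicom <- function(path, pixels, spacing = c(1.5, 1.5)) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                              endian = "little")
  elem_short <- function(group, el, vr, value) {
    if (length(value) %% 2L == 1L && is.raw(value))
      value <- c(value, as.raw(0x20))
    c(u16(group), u16(el), charToRaw(vr), u16(length(value)), value)
  }
  elem_ow <- function(group, el, value) {
    c(u16(group), u16(el), charToRaw("OW"), u16(0), u32(length(value)), value)
  }
  px <- as.integer(round(t(pixels)))  # row-major pixel order
  pxraw <- writeBin(px, raw(), size = 2L, endian = "little")
  body <- c(
    elem_short(0x0028, 0x0008, "IS", charToRaw("1")),
    elem_short(0x0028, 0x0010, "US", u16(nrow(pixels))),
    elem_short(0x0028, 0x0011, "US", u16(ncol(pixels))),
    elem_short(0x0028, 0x0030, "DS",
               charToRaw(sprintf("%g\\%g", spacing[2], spacing[1]))),
    elem_short(0x0028, 0x0100, "US", u16(16L)),
    elem_short(0x0028, 0x0103, "US", u16(0L)),
    elem_ow(0x7FE0, 0x0010, pxraw))
  con <- file(path, "wb")
  writeBin(c(raw(128L), charToRaw("DICM"), body), con)
  close(con)
  path
}
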