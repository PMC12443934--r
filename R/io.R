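# Image dispatch, report serialization, ground-truth sidecars, fixtures.

#' Read an image file as a slice image
#'
#' Dispatches on extension: `.nii` (NIfTI-1), `.png` (8/16-bit grayscale),
#' `.dcm`/`.ima` (single-frame DICOM). PNG carries no physical spacing, so a
#' `spacing` override is mandatory for it; for the other formats the override
#' wins over the header when given.
#'
#' @param path image file.
#' @param spacing optional mm-per-pixel `(x, y)` override.
#' @param plane orientation label to attach.
#' @param max_intensity for PNG: full-scale intensity the 16-bit code 65535
#'   maps back to (default 1: pixels in `[0, 1]`).
#' @return a `slice_image`.
#' @export
read_image <- function(path, spacing = NULL, plane = "coronal",
                       max_intensity = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    nii = read_nifti(path, plane = plane),
    png = {
      if (is.null(spacing))
        stop_format("PNG has no physical pixel spacing; supply `spacing` in mm")
      px <- png::readPNG(path)
      if (length(dim(px)) == 3L) px <- px[, , 1]
      slice_image(px * max_intensity, spacing_xy = spacing, plane = plane,
                  meta = list(source = path, format = "png"))
    },
    dcm = ,
    ima = read_dicom(path, spacing = spacing, plane = plane),
    stop_format(sprintf("unsupported image format '.%s'", ext)))
  if (!is.null(spacing)) {
    img$spacing_xy <- rep_len(as.numeric(spacing), 2L)
    img$origin_world <- -(c(ncol(img$pixels), nrow(img$pixels)) - 1) / 2 *
      img$spacing_xy
  }
  img
}

#' Write a QA report
#'
#' JSON output is schema-versioned and round-trips through [read_report()].
#' CSV output has one row per scan in the conventional table order:
#' consecutive distances, their average, SNR, CNR, with distances and average
#' printed at 0.1 mm precision.
#'
#' @param report a [qa_report()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (!inherits(report, "qa_report")) stop_validation("not a qa_report")
  if (length(report$distances) == 0L)
    stop_insufficient("report holds no distances")
  if (format == "json") {
    payload <- list(
      schema = "phantomqa-report-1",
      distances_mm = report$distances,
      average_distance_mm = report$average_distance,
      snr = report$snr, cnr = report$cnr,
      pixel_spacing_mm = report$pixel_spacing,
      regions = lapply(report$regions, unclass),
      provenance = report$provenance)
    ok <- tryCatch({
      jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
      TRUE
    }, error = function(e) {
      stop_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
    })
  } else {
    n <- length(report$distances)
    row <- c(sprintf("%.1f", report$distances),
             sprintf("%.1f", report$average_distance),
             sprintf("%.6g", report$snr), sprintf("%.6g", report$cnr))
    hdr <- c(sprintf("dist_%d_%d_mm", seq_len(n), seq_len(n) + 1L),
             "average_mm", "snr", "cnr")
    ok <- tryCatch({
      writeLines(c(paste(hdr, collapse = ","),
                   paste(row, collapse = ",")), path)
      TRUE
    }, error = function(e) {
      stop_io(sprintf("cannot write '%s': %s", path, conditionMessage(e)))
    })
  }
  invisible(path)
}

#' Read back a JSON QA report
#'
#' @param path file produced by [write_report()] with `format = "json"`.
#' @return a [qa_report()].
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("'%s' not found", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "phantomqa-report-1"))
    stop_format(sprintf("'%s' is not a phantomqa report", path))
  regions <- list()
  if (length(j$regions)) {
    regions <- lapply(seq_len(nrow(j$regions)), function(i) {
      region_spec(j$regions$kind[i],
                  top_left = unlist(j$regions$top_left[i]),
                  size = unlist(j$regions$size[i]),
                  placement = j$regions$placement[i])
    })
  }
  qa_report(j$distances_mm, snr = j$snr, cnr = j$cnr, regions = regions,
            pixel_spacing = j$pixel_spacing_mm,
            provenance = as.list(j$provenance))
}

#' Write the ground-truth sidecar for a simulated slice
#'
#' @param image a `slice_image` produced by [render_slice()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_sidecar <- function(image, path) {
  gt <- image$meta$ground_truth
  if (is.null(gt)) stop_validation("image carries no ground truth")
  payload <- list(
    schema = "phantomqa-sidecar-1",
    plane = image$plane,
    spacing_mm = image$spacing_xy,
    origin_world_mm = image$origin_world,
    sequence = image$meta$sequence,
    noise = image$meta$noise,
    distortion = image$meta$distortion,
    geometry_hash = image$meta$geometry_hash,
    ground_truth = gt)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth sidecar
#'
#' @param path JSON file written by [write_sidecar()].
#' @return list with the sidecar fields; `$ground_truth` is a data frame.
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("'%s' not found", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, "phantomqa-sidecar-1"))
    stop_format(sprintf("'%s' is not a phantomqa sidecar", path))
  j
}

#' Build the four-scan synthetic fixture set
#'
#' Emulates the four-scan experiment the phantom is designed for: T1-weighted
#' and T2-weighted coronal acquisitions with the flat top, and the same pair
#' with the domed top after a small rigid re-placement. Within each top-style
#' pair the phantom placement is identical (the precondition for a valid
#' distortion comparison); across top styles it differs. Noise scales are
#' chosen so the measured T1-weighted SNR is of order 10^2 and the
#' T2-weighted SNR of order 10^3, reproducing the order-of-magnitude gap
#' between the two protocols.
#'
#' @param seed integer; all four scans derive their noise seeds from it, so
#'   fixture images are byte-identical across runs with the same seed.
#' @param dir optional directory: when given, each scan is written as
#'   `<name>.nii` plus `<name>_truth.json` sidecar.
#' @param sample_layout,spacing forwarded to [build_default_phantom()].
#' @return object of class `fixture_set`: list with `seed` and `scans`, a
#'   named list (`t1w_flat`, `t2w_flat`, `t1w_domed`, `t2w_domed`) of lists
#'   holding `image`, `mode`, `top_style` and `geometry`.
#' @export
make_fixtures <- function(seed = 1L, dir = NULL,
                          sample_layout = c("oil", "cu1", "cu2", "cu3"),
                          spacing = 24) {
  seed <- as.integer(seed)
  # domed placement: small rigid move (2 deg out-of-plane, 3 deg in-plane)
  geom_flat <- build_default_phantom("flat", "cor_sag", sample_layout,
                                     spacing = spacing)
  geom_domed <- build_default_phantom("domed", "cor_sag", sample_layout,
                                      spacing = spacing,
                                      tilt = c(2, 3, 0))
  sigma <- c(t1w = 10, t2w = 1.75)
  specs <- list(
    t1w_flat  = list(geom = geom_flat,  preset = "t1w_coronal", mode = "t1w"),
    t2w_flat  = list(geom = geom_flat,  preset = "t2w_coronal", mode = "t2w"),
    t1w_domed = list(geom = geom_domed, preset = "t1w_coronal", mode = "t1w"),
    t2w_domed = list(geom = geom_domed, preset = "t2w_coronal", mode = "t2w"))
  scans <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    nm <- names(specs)[i]
    nz <- noise_model("rician", sigma = sigma[[sp$mode]],
                      seed = (seed %% 100000L) * 10L + i)
    img <- render_slice(sp$geom, sequence_preset(sp$preset),
                        noise = nz)
    scans[[nm]] <- list(name = nm, image = img, mode = sp$mode,
                        top_style = sp$geom$top_style, geometry = sp$geom)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_nifti(img, file.path(dir, paste0(nm, ".nii")))
      write_sidecar(img, file.path(dir, paste0(nm, "_truth.json")))
    }
  }
  structure(list(seed = seed, scans = scans), class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf("<fixture_set> seed %d, %d scans: %s\n", x$seed,
              length(x$scans), paste(names(x$scans), collapse = ", ")))
  invisible(x)
}
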