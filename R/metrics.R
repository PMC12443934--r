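# The three image-quality measurands: one-dimensional geometric distortion
# via consecutive inter-vial distances, SNR and CNR from rectangular
# signal/noise regions.

#' Define a rectangular signal or noise region
#'
#' @param kind `"noise"` or `"signal"`.
#' @param top_left 0-based pixel index pair `(col, row)` of the region's
#'   top-left corner.
#' @param size pixel pair `(width, height)`; the conventional sizes are
#'   10 x 10 for noise and 5 x 5 for signal regions.
#' @param placement `"manual"` or `"auto"`.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(kind = c("noise", "signal"), top_left,
                        size = if (match.arg(kind) == "noise") c(10, 10)
                               else c(5, 5),
                        placement = "manual") {
  kind <- match.arg(kind)
  top_left <- as.integer(rep_len(top_left, 2L))
  size <- as.integer(rep_len(size, 2L))
  if (any(size < 1L)) stop_validation("region size must be at least 1 pixel")
  if (any(top_left < 0L)) stop_validation("top_left must be non-negative")
  structure(list(kind = kind, top_left = top_left, size = size,
                 placement = placement),
            class = "region_spec")
}

.region_pixels <- function(image, region) {
  cols <- region$top_left[1] + seq_len(region$size[1]) - 1L + 1L
  rows <- region$top_left[2] + seq_len(region$size[2]) - 1L + 1L
  if (max(rows) > nrow(image$pixels) || max(cols) > ncol(image$pixels))
    stop_validation(sprintf(
      "%s region at (%d, %d) size (%d x %d) exceeds the %d x %d image",
      region$kind, region$top_left[1], region$top_left[2],
      region$size[1], region$size[2],
      ncol(image$pixels), nrow(image$pixels)))
  as.numeric(image$pixels[rows, cols])
}

#' Consecutive inter-vial distances
#'
#' Euclidean distance in mm between the world-coordinate centres of
#' consecutive ROIs, in the along-row order produced by [order_vials()].
#'
#' @param rois ordered `vial_rois` data frame (needs `x_mm`, `y_mm`), or a
#'   two-column matrix of centres in mm.
#' @param spacing unused when world coordinates are present; kept so pixel
#'   centres can be supplied as a matrix scaled by `spacing` mm/px.
#' @return numeric vector of length `n - 1`.
#' @export
inter_vial_distances <- function(rois, spacing = 1) {
  if (is.matrix(rois)) {
    xy <- rois * spacing
  } else {
    xy <- cbind(rois$x_mm, rois$y_mm)
  }
  if (nrow(xy) < 2L)
    stop_insufficient("need at least 2 ROIs to compute inter-vial distances")
  sqrt(rowSums((xy[-1, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
}

#' Average inter-vial distance
#'
#' @param distances non-empty numeric vector of mm distances.
#' @return arithmetic mean, mm.
#' @export
average_distance <- function(distances) {
  if (length(distances) == 0L)
    stop_insufficient("no distances to average")
  mean(distances)
}

#' Signal-to-noise ratio
#'
#' Mean of the signal-region pixels divided by the sample (n - 1) standard
#' deviation of the pooled noise-region pixels. No Rician bias correction is
#' applied; a corrected estimate (dividing instead by
#' `sd / sqrt(2 - pi/2)`, valid when the noise regions are air) is attached
#' as attribute `"rician_corrected"` for information.
#'
#' @param image a `slice_image`.
#' @param signal one signal [region_spec()].
#' @param noise list of one or more noise [region_spec()]s; their pixels are
#'   pooled.
#' @return non-negative scalar.
#' @export
compute_snr <- function(image, signal, noise) {
  st <- .signal_noise_stats(image, signal, noise)
  out <- st$signal_mean / st$noise_sd
  attr(out, "rician_corrected") <-
    st$signal_mean / (st$noise_sd / sqrt(2 - pi / 2))
  out
}

#' Contrast-to-noise ratio
#'
#' (signal mean - pooled noise mean) / pooled noise standard deviation.
#'
#' @inheritParams compute_snr
#' @return scalar (can be negative if the signal region is darker than the
#'   noise mean).
#' @export
compute_cnr <- function(image, signal, noise) {
  st <- .signal_noise_stats(image, signal, noise)
  (st$signal_mean - st$noise_mean) / st$noise_sd
}

.signal_noise_stats <- function(image, signal, noise) {
  if (!inherits(signal, "region_spec") || signal$kind != "signal")
    stop_validation("exactly one signal region_spec is required")
  if (inherits(noise, "region_spec")) noise <- list(noise)
  if (!length(noise)) stop_validation("at least one noise region is required")
  for (r in noise) if (r$kind != "noise")
    stop_validation("noise regions must have kind 'noise'")
  spx <- .region_pixels(image, signal)
  npx <- unlist(lapply(noise, .region_pixels, image = image))
  nsd <- stats::sd(npx)
  if (!is.finite(nsd) || nsd == 0)
    stop_validation("undefined SNR: noise standard deviation is zero")
  list(signal_mean = mean(spx), noise_mean = mean(npx), noise_sd = nsd)
}

#' Automatically place the signal and noise regions
#'
#' Reconstructs the conventional placements: for T1-weighted images the 5 x 5
#' signal region is centred on the vial with the highest interior mean (the
#' oil vial under the default materials); for T2-weighted images it is placed
#' in a central portion of the background water fill, outside every detected
#' vial disk dilated by 2 pixels. Two 10 x 10 noise regions go in opposite
#' image corners, inset by a 3-pixel margin, and are slid along the border if
#' they touch the thresholded foreground.
#'
#' @param image a `slice_image`.
#' @param rois ordered `vial_rois` (required for `mode = "t1w"`).
#' @param mode `"t1w"` or `"t2w"`.
#' @return list with elements `signal` (a [region_spec()]) and `noise`
#'   (list of two [region_spec()]s).
#' @export
auto_place_regions <- function(image, rois = NULL, mode = c("t1w", "t2w")) {
  mode <- match.arg(mode)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  thr <- otsu_threshold(px)
  fg <- px >= thr

  if (mode == "t1w") {
    if (is.null(rois) || nrow(rois) == 0L)
      stop_validation("t1w region placement needs at least one detected ROI")
    means <- vapply(seq_len(nrow(rois)), function(i) {
      r_px <- rois$radius_mm[i] / mean(image$spacing_xy)
      .disk_mean(px, rois$col_px[i], rois$row_px[i], max(r_px * 0.6, 1.5))
    }, numeric(1))
    b <- which.max(means)
    tl <- c(round(rois$col_px[b]) - 2L, round(rois$row_px[b]) - 2L)
    tl <- pmin(pmax(tl, 0L), c(nc, nr) - 5L)
    sig <- region_spec("signal", tl, c(5, 5), placement = "auto")
  } else {
    sig <- .t2w_signal_region(image, rois, fg)
  }

  # clearance mask for noise windows: anything structured, including
  # partial-volume edge pixels well below the Otsu threshold
  noise <- .corner_noise_regions(px >= 0.25 * thr)
  list(signal = sig, noise = noise)
}

.disk_mean <- function(px, cx, cy, r_px) {
  nr <- nrow(px); nc <- ncol(px)
  cols <- max(1L, floor(cx - r_px) + 1L):min(nc, ceiling(cx + r_px) + 1L)
  rows <- max(1L, floor(cy - r_px) + 1L):min(nr, ceiling(cy + r_px) + 1L)
  sub <- px[rows, cols, drop = FALSE]
  d2 <- outer((rows - 1L) - cy, (cols - 1L) - cx,
              function(a, b) a^2 + b^2)
  mean(sub[d2 <= r_px^2])
}

.t2w_signal_region <- function(image, rois, fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  if (!any(fg)) stop_placement("no foreground found for signal placement")
  # centroid of the phantom foreground, 0-based
  idx <- which(fg)
  c0 <- mean((idx - 1L) %/% nr)
  r0 <- mean((idx - 1L) %% nr)
  dil_px <- 2
  ok_center <- function(cc, rr) {
    tl <- c(round(cc) - 2L, round(rr) - 2L)
    if (any(tl < 0L) || tl[1] + 5L > nc || tl[2] + 5L > nr) return(NULL)
    sub <- fg[tl[2] + 1:5, tl[1] + 1:5]
    if (!all(sub)) return(NULL)  # must sit inside the fill
    if (!is.null(rois) && nrow(rois)) {
      corners_c <- tl[1] + c(0, 4, 0, 4, 2)
      corners_r <- tl[2] + c(0, 0, 4, 4, 2)
      for (i in seq_len(nrow(rois))) {
        r_px <- rois$radius_mm[i] / mean(image$spacing_xy) + dil_px
        if (any((corners_c - rois$col_px[i])^2 +
                (corners_r - rois$row_px[i])^2 <= r_px^2)) return(NULL)
      }
    }
    tl
  }
  # spiral search outward from the centroid
  for (rad in 0:max(nr, nc)) {
    if (rad == 0) cand <- cbind(c0, r0)
    else {
      t <- seq(0, 2 * pi, length.out = 8 * rad + 1)[-1]
      cand <- cbind(c0 + rad * cos(t), r0 + rad * sin(t))
    }
    for (i in seq_len(nrow(cand))) {
      tl <- ok_center(cand[i, 1], cand[i, 2])
      if (!is.null(tl))
        return(region_spec("signal", tl, c(5, 5), placement = "auto"))
    }
  }
  stop_placement("no 5x5 background-fill position found; supply a manual signal region")
}

.dilate3 <- function(m, times = 1L) {
  nr <- nrow(m); nc <- ncol(m)
  for (k in seq_len(times)) {
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- m
    out <- matrix(FALSE, nr, nc)
    for (i in 0:2) for (j in 0:2)
      out <- out | p[(1:nr) + i, (1:nc) + j]
    m <- out
  }
  m
}

.corner_noise_regions <- function(fg) {
  # dilate so partial-volume pixels at the phantom edge (below threshold but
  # structured) cannot leak into a "clear" noise window
  fg <- .dilate3(fg, 2L)
  nr <- nrow(fg); nc <- ncol(fg)
  margin <- 3L; sz <- 10L
  clear <- function(tl) {
    if (any(tl < 0L) || tl[1] + sz > nc || tl[2] + sz > nr) return(FALSE)
    !any(fg[tl[2] + 1:sz, tl[1] + 1:sz])
  }
  pick <- function(start, step) {
    tl <- start
    for (k in 0:max(nr, nc)) {
      cand <- start + k * step
      if (clear(cand)) return(cand)
    }
    NULL
  }
  # opposite corners: top-left sliding right, bottom-right sliding left
  a <- pick(c(margin, margin), c(1L, 0L))
  b <- pick(c(nc - margin - sz, nr - margin - sz), c(-1L, 0L))
  if (is.null(a) || is.null(b))
    stop_placement("no corner noise placement is free of foreground; supply manual regions")
  list(region_spec("noise", a, c(sz, sz), placement = "auto"),
       region_spec("noise", b, c(sz, sz), placement = "auto"))
}

#' Assemble a QA report for one analysed image
#'
#' @param distances consecutive inter-vial distances, mm.
#' @param snr,cnr scalars from [compute_snr()] / [compute_cnr()].
#' @param regions list of the [region_spec()]s used.
#' @param pixel_spacing mm per pixel (scalar or pair).
#' @param provenance list recording inputs, parameters, seed.
#' @return object of class `qa_report`; `average_distance` is always the
#'   exact arithmetic mean of `distances`.
#' @export
qa_report <- function(distances, snr = NA_real_, cnr = NA_real_,
                      regions = list(), pixel_spacing, provenance = list()) {
  if (length(distances) == 0L)
    stop_insufficient("a QA report needs at least one inter-vial distance")
  if (any(distances <= 0))
    stop_validation("inter-vial distances must be positive")
  structure(list(distances = as.numeric(distances),
                 average_distance = mean(distances),
                 snr = as.numeric(snr), cnr = as.numeric(cnr),
                 regions = regions,
                 pixel_spacing = as.numeric(pixel_spacing)[1],
                 provenance = provenance),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report>\n")
  cat(sprintf("  distances (mm): %s\n",
              paste(sprintf("%.1f", x$distances), collapse = ", ")))
  cat(sprintf("  average (mm):   %.1f\n", x$average_distance))
  cat(sprintf("  SNR: %.0f   CNR: %.0f\n", x$snr, x$cnr))
  cat(sprintf("  pixel spacing: %.2f mm\n", x$pixel_spacing))
  invisible(x)
}

#' Compare the distortion metric of two scans
#'
#' Valid only when the phantom placement was unchanged between the two
#' acquisitions (same-session scans); that assumption is the caller's to
#' assert and is recorded in the result.
#'
#' @param report_a,report_b two [qa_report()]s.
#' @return list with `difference` (mm, absolute difference of the average
#'   inter-vial distances), `relative_percent` (difference over the mean of
#'   the two averages, percent), and `within_pixel` (TRUE when the difference
#'   does not exceed the smaller of the two pixel spacings).
#' @export
compare_scans <- function(report_a, report_b) {
  d <- abs(report_a$average_distance - report_b$average_distance)
  m <- mean(c(report_a$average_distance, report_b$average_distance))
  list(difference = d,
       relative_percent = 100 * d / m,
       within_pixel = d <= min(report_a$pixel_spacing,
                               report_b$pixel_spacing))
}

#' Full analysis of one slice: detect, measure, report
#'
#' Convenience wrapper running [detect_vials()], [inter_vial_distances()],
#' region placement and [compute_snr()]/[compute_cnr()].
#'
#' @param image a `slice_image`.
#' @param mode `"t1w"` or `"t2w"` (drives the signal-region placement).
#' @param params a [detection_params()].
#' @param regions optional manual list with elements `signal` and `noise`
#'   (bypasses auto placement).
#' @param rois optional precomputed `vial_rois` (bypasses detection).
#' @return a [qa_report()].
#' @export
analyze_slice <- function(image, mode = c("t1w", "t2w"),
                          params = detection_params(), regions = NULL,
                          rois = NULL) {
  mode <- match.arg(mode)
  if (is.null(rois)) rois <- detect_vials(image, params)
  dists <- inter_vial_distances(rois)
  if (is.null(regions)) regions <- auto_place_regions(image, rois, mode)
  snr <- compute_snr(image, regions$signal, regions$noise)
  cnr <- compute_cnr(image, regions$signal, regions$noise)
  qa_report(dists, snr = snr, cnr = cnr,
            regions = c(list(regions$signal), regions$noise),
            pixel_spacing = mean(image$spacing_xy),
            provenance = list(mode = mode,
                              geometry_hash = image$meta$geometry_hash,
                              n_rois = nrow(rois)))
}
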