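# Spin-echo magnitude-image simulator.
#
# Intensities are arbitrary units scaled so that a fully recovered pd = 1
# sample gives 1000. Signal averaging enters only through the effective noise
# scale sigma / sqrt(averages); no per-average simulation.

INTENSITY_SCALE <- 1000

#' Acquisition parameters for one scan
#'
#' @param family `"ir_se"` (inversion-recovery spin echo, T1 weighting) or
#'   `"se"` (spin echo / fast spin echo with an effective echo time, T2
#'   weighting).
#' @param tr repetition time, s.
#' @param te echo time, s (effective TE for `"se"`).
#' @param ti inversion time, s (`"ir_se"` only).
#' @param averages number of signal averages (NEX).
#' @param fov_xy field of view per in-plane axis `(x, y)`, mm.
#' @param resolution_xy pixel spacing per in-plane axis, mm.
#' @param slice_thickness mm.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return an object of class `sequence_params`.
#' @export
sequence_params <- function(family = c("ir_se", "se"), tr, te, ti = NA_real_,
                            averages = 1L, fov_xy = c(180, 180),
                            resolution_xy = c(1.5, 1.5),
                            slice_thickness = 5,
                            plane = c("coronal", "axial", "sagittal")) {
  family <- match.arg(family)
  plane <- match.arg(plane)
  if (!(tr > te && te >= 0)) stop_validation("need tr > te >= 0")
  if (family == "ir_se") {
    if (!is.finite(ti) || !(ti > 0 && ti < tr))
      stop_validation("ir_se needs 0 < ti < tr")
  } else ti <- NA_real_
  if (averages < 1) stop_validation("averages must be >= 1")
  fov_xy <- rep_len(as.numeric(fov_xy), 2L)
  resolution_xy <- rep_len(as.numeric(resolution_xy), 2L)
  if (any(fov_xy <= 0) || any(resolution_xy <= 0))
    stop_validation("fov and resolution must be positive")
  structure(list(family = family, tr = tr, te = te, ti = ti,
                 averages = as.integer(averages), fov_xy = fov_xy,
                 resolution_xy = resolution_xy,
                 slice_thickness = slice_thickness, plane = plane),
            class = "sequence_params")
}

#' Built-in sequence presets for the 64 mT protocol
#'
#' `"t1w_coronal"`/`"t1w_axial"`: multi-slice IR-SE, TR 1.5 s, TI 0.3 s,
#' TE 0.006 s, 24 averages, 1.6 mm resolution. `"t2w_coronal"`/`"t2w_axial"`:
#' 3D FSE modelled by its effective TE (0.231 s coronal, 0.203 s axial),
#' TR 2 s, 80 averages, 1.5 mm resolution. Fields of view are 180 mm
#' left/right and superior/inferior and 220 mm anterior/posterior; slices are
#' 5 mm.
#'
#' @param name preset name.
#' @return a [sequence_params()].
#' @export
sequence_preset <- function(name = c("t1w_coronal", "t2w_coronal",
                                     "t1w_axial", "t2w_axial")) {
  name <- match.arg(name)
  switch(name,
    t1w_coronal = sequence_params("ir_se", tr = 1.5, te = 0.006, ti = 0.3,
                                  averages = 24L, fov_xy = c(180, 180),
                                  resolution_xy = c(1.6, 1.6),
                                  plane = "coronal"),
    t2w_coronal = sequence_params("se", tr = 2, te = 0.231,
                                  averages = 80L, fov_xy = c(180, 180),
                                  resolution_xy = c(1.5, 1.5),
                                  plane = "coronal"),
    t1w_axial   = sequence_params("ir_se", tr = 1.5, te = 0.006, ti = 0.3,
                                  averages = 24L, fov_xy = c(180, 220),
                                  resolution_xy = c(1.6, 1.6),
                                  plane = "axial"),
    t2w_axial   = sequence_params("se", tr = 2, te = 0.203,
                                  averages = 80L, fov_xy = c(180, 220),
                                  resolution_xy = c(1.5, 1.5),
                                  plane = "axial"))
}

#' Inversion-recovery spin-echo signal
#'
#' Magnitude signal `pd * |1 - 2 exp(-TI/T1) + exp(-TR/T1)| * exp(-TE/T2)`,
#' scaled to intensity units (fully recovered pd = 1 gives 1000).
#'
#' @param material a [material_sample()].
#' @param seq a [sequence_params()] with `family = "ir_se"`.
#' @return non-negative intensity.
#' @export
ir_se_signal <- function(material, seq) {
  if (seq$family != "ir_se")
    stop_usage("ir_se_signal needs a sequence with family 'ir_se'")
  s <- material$pd *
    abs(1 - 2 * exp(-seq$ti / material$t1) + exp(-seq$tr / material$t1)) *
    exp(-seq$te / material$t2)
  INTENSITY_SCALE * s
}

#' Spin-echo signal (effective-TE mono-exponential model)
#'
#' Magnitude signal `pd * (1 - exp(-TR/T1)) * exp(-TE/T2)`, scaled to
#' intensity units. Echo-train, B1 and slice-profile effects of the scanner's
#' 3D FSE are not modelled.
#'
#' @inheritParams ir_se_signal
#' @export
se_signal <- function(material, seq) {
  if (seq$family != "se")
    stop_usage("se_signal needs a sequence with family 'se'")
  s <- material$pd * (1 - exp(-seq$tr / material$t1)) *
    exp(-seq$te / material$t2)
  INTENSITY_SCALE * s
}

material_signal <- function(material, seq) {
  if (seq$family == "ir_se") ir_se_signal(material, seq)
  else se_signal(material, seq)
}

#' Describe the image noise
#'
#' @param kind `"none"`, `"gaussian"` (additive, truncated at zero) or
#'   `"rician"` (the magnitude-image noise model; reduces to Rayleigh where
#'   the true signal is zero).
#' @param sigma noise scale in intensity units, per single average; the
#'   simulator applies `sigma / sqrt(averages)`.
#' @param seed integer seed making the noise reproducible.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian", "rician"), sigma = 0,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop_validation("sigma must be a finite non-negative scalar")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Describe a geometric distortion of the image coordinates
#'
#' The field maps true world coordinates to observed (distorted) world
#' coordinates; ground-truth centres and the rendered image are warped through
#' the same map, so the pair stays consistent.
#'
#' @param kind `"identity"`, `"affine"` (`w = A u + b`) or `"radial"`
#'   (`w = u * (1 + k |u|^2)`, barrel/pincushion).
#' @param A 2x2 matrix (affine).
#' @param b length-2 offset, mm (affine).
#' @param k radial coefficient, 1/mm^2.
#' @return an object of class `distortion_field`.
#' @export
distortion_field <- function(kind = c("identity", "affine", "radial"),
                             A = diag(2), b = c(0, 0), k = 0) {
  kind <- match.arg(kind)
  if (kind == "affine") {
    A <- matrix(as.numeric(A), 2, 2)
    if (abs(det(A)) < 1e-9)
      stop_validation("affine distortion must be invertible")
  }
  structure(list(kind = kind, A = A, b = as.numeric(b), k = as.numeric(k)),
            class = "distortion_field")
}

# forward map: true -> observed, on an n x 2 matrix of mm coordinates
distort_forward <- function(field, xy) {
  switch(field$kind,
    identity = xy,
    affine = sweep(xy %*% t(field$A), 2, field$b, `+`),
    radial = xy * (1 + field$k * rowSums(xy^2)))
}

# inverse map: observed -> true
distort_inverse <- function(field, xy) {
  switch(field$kind,
    identity = xy,
    affine = sweep(xy, 2, field$b, `-`) %*% t(solve(field$A)),
    radial = {
      # solve r_obs = r (1 + k r^2) for r by Newton iteration per pixel
      r_obs <- sqrt(rowSums(xy^2))
      r <- r_obs
      for (it in 1:25) {
        f <- r * (1 + field$k * r^2) - r_obs
        fp <- 1 + 3 * field$k * r^2
        if (any(fp <= 0))
          stop_validation("radial distortion not invertible over the image footprint")
        r <- r - f / fp
      }
      if (max(abs(r * (1 + field$k * r^2) - r_obs)) > 1e-6)
        stop_validation("radial distortion not invertible over the image footprint")
      scl <- ifelse(r_obs > 0, r / r_obs, 1)
      xy * scl
    })
}

#' Construct a 2D magnitude slice image
#'
#' @param pixels numeric matrix (rows = image rows = y, columns = x),
#'   non-negative intensities.
#' @param spacing_xy mm per pixel, `(x, y)`.
#' @param origin_world mm world position of the centre of pixel `[1, 1]`
#'   (0-based index (0,0)), `(x, y)`.
#' @param plane orientation label.
#' @param meta provenance list (sequence, noise, distortion, geometry hash).
#' @return an object of class `slice_image`.
#' @export
slice_image <- function(pixels, spacing_xy, origin_world = NULL,
                        plane = "coronal", meta = list()) {
  if (!is.matrix(pixels)) stop_validation("pixels must be a matrix")
  spacing_xy <- rep_len(as.numeric(spacing_xy), 2L)
  if (any(spacing_xy <= 0)) stop_validation("pixel spacing must be positive")
  if (is.null(origin_world)) {
    # centre the FOV on the world origin (pixel-centre convention)
    origin_world <- -(c(ncol(pixels), nrow(pixels)) - 1) / 2 * spacing_xy
  }
  structure(list(pixels = pixels, spacing_xy = spacing_xy,
                 origin_world = as.numeric(origin_world), plane = plane,
                 meta = meta),
            class = "slice_image")
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf(
    "<slice_image> %d x %d px, spacing (%.3g, %.3g) mm, plane %s, range [%.3g, %.3g]\n",
    nrow(x$pixels), ncol(x$pixels), x$spacing_xy[1], x$spacing_xy[2],
    x$plane, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# world (x, y) mm of fractional 0-based pixel indices (col0, row0)
pixel_to_world <- function(img, col0, row0) {
  cbind(img$origin_world[1] + col0 * img$spacing_xy[1],
        img$origin_world[2] + row0 * img$spacing_xy[2])
}

world_to_pixel <- function(img, xy) {
  cbind((xy[, 1] - img$origin_world[1]) / img$spacing_xy[1],
        (xy[, 2] - img$origin_world[2]) / img$spacing_xy[2])
}

#' Render a 2D magnitude slice of the digital phantom
#'
#' Every pixel takes the closed-form signal of the material found at its
#' (inverse-distorted) world coordinate: vial interiors at their material
#' signal, tube-wall annuli and the printed shell at zero (no mobile protons),
#' background water at the water signal, exterior air at zero. Edges are
#' anti-aliased by subpixel supersampling. Ground-truth vial circles are
#' passed through the same distortion, so image and truth warp together.
#'
#' @param geometry a `phantom_geometry`.
#' @param seq a [sequence_params()].
#' @param distortion a [distortion_field()].
#' @param noise a [noise_model()]; the applied scale is
#'   `sigma / sqrt(averages)`.
#' @param slice_offset slice position along the plane normal, mm.
#' @param supersample subpixel samples per axis for anti-aliasing.
#' @return a `slice_image`; its `meta$ground_truth` holds the data frame of
#'   true vial circles with both world (`u_mm`, `v_mm`) and 0-based pixel
#'   (`col_px`, `row_px`, `radius_px`) coordinates.
#' @export
render_slice <- function(geometry, seq, distortion = distortion_field(),
                         noise = noise_model(), slice_offset = 0,
                         supersample = 4L) {
  ncol_px <- round(seq$fov_xy[1] / seq$resolution_xy[1])
  nrow_px <- round(seq$fov_xy[2] / seq$resolution_xy[2])

  gt <- ground_truth_centers(geometry, plane = seq$plane,
                             slice_offset = slice_offset)
  if (nrow(gt) == 0)
    stop_geometry("slice plane does not intersect any vial row; check plane/offset")

  img <- slice_image(matrix(0, nrow_px, ncol_px),
                     spacing_xy = seq$resolution_xy, plane = seq$plane)

  # signals per material
  sig_bg <- material_signal(geometry$background, seq)
  sig_vial <- vapply(gt$vial, function(i)
    material_signal(geometry$vials[[i]]$material, seq), numeric(1))

  # subpixel sample offsets within one pixel, in pixel units
  ss <- supersample
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  grid_off <- expand.grid(dx = off, dy = off)

  fr <- .plane_frame(seq$plane)
  Rt <- t(tilt_matrix(geometry$tilt))  # scanner -> phantom frame
  r_in <- geometry$inner_diameter / 2
  half_len <- geometry$body_length / 2  # the liquid fill is the body interior

  col0 <- rep(seq_len(ncol_px) - 1L, each = nrow_px)
  row0 <- rep(seq_len(nrow_px) - 1L, times = ncol_px)
  acc <- numeric(nrow_px * ncol_px)

  for (k in seq_len(nrow(grid_off))) {
    w <- pixel_to_world(img, col0 + grid_off$dx[k], row0 + grid_off$dy[k])
    u <- distort_inverse(distortion, w)  # observed -> true world
    # phantom interior test (exact, through the tilt)
    p3 <- cbind(u[, 1] * fr$u[1] + u[, 2] * fr$v[1] + slice_offset * fr$n[1],
                u[, 1] * fr$u[2] + u[, 2] * fr$v[2] + slice_offset * fr$n[2],
                u[, 1] * fr$u[3] + u[, 2] * fr$v[3] + slice_offset * fr$n[3])
    q <- p3 %*% t(Rt)  # rows become Rt %*% p: scanner -> phantom frame
    val <- ifelse(q[, 1]^2 + q[, 2]^2 <= r_in^2 & abs(q[, 3]) <= half_len,
                  sig_bg, 0)
    # vials: projected circles (interior signal, wall annulus at zero)
    for (j in seq_len(nrow(gt))) {
      d2 <- (u[, 1] - gt$u_mm[j])^2 + (u[, 2] - gt$v_mm[j])^2
      inside <- d2 <= gt$inner_radius_mm[j]^2
      wall <- !inside & d2 <= gt$outer_radius_mm[j]^2
      val[inside] <- sig_vial[j]
      val[wall] <- 0
    }
    acc <- acc + val
  }
  img$pixels <- matrix(acc / nrow(grid_off), nrow_px, ncol_px)

  # ground truth in observed (distorted) coordinates
  obs <- distort_forward(distortion, cbind(gt$u_mm, gt$v_mm))
  gt$u_mm <- obs[, 1]
  gt$v_mm <- obs[, 2]
  px <- world_to_pixel(img, obs)
  gt$col_px <- px[, 1]
  gt$row_px <- px[, 2]
  gt$radius_px <- gt$radius_mm / mean(seq$resolution_xy)

  img$meta <- list(
    sequence = unclass(seq), noise = unclass(noise),
    distortion = list(kind = distortion$kind),
    slice_offset = slice_offset, supersample = ss,
    geometry_hash = geometry_hash(geometry),
    ground_truth = gt)
  add_noise(img, noise, averages = seq$averages)
}

# cheap content hash for provenance (no digest dependency)
geometry_hash <- function(geometry) {
  s <- paste(utils::capture.output(utils::str(geometry, digits.d = 10)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 977)) %%
            .Machine$integer.max)
}

#' Apply the noise model to a slice
#'
#' Gaussian noise is additive and truncated at zero; Rician noise is
#' `sqrt((S + n1)^2 + n2^2)` with independent `n1, n2 ~ N(0, sigma^2)`, the
#' standard model for magnitude MR images (Rayleigh in air). The same seed
#' gives a bit-identical result; the caller's RNG state is left untouched.
#'
#' @param image a `slice_image`.
#' @param noise a [noise_model()].
#' @param averages if supplied, the applied scale is
#'   `sigma / sqrt(averages)`.
#' @return the noisy `slice_image`.
#' @export
add_noise <- function(image, noise, averages = 1L) {
  if (noise$kind == "none" || noise$sigma == 0) return(image)
  sig <- noise$sigma / sqrt(averages)
  n <- length(image$pixels)
  image$pixels <- withr::with_seed(noise$seed, {
    if (noise$kind == "gaussian") {
      pmax(image$pixels + matrix(stats::rnorm(n, 0, sig), nrow(image$pixels)), 0)
    } else {
      n1 <- matrix(stats::rnorm(n, 0, sig), nrow(image$pixels))
      n2 <- matrix(stats::rnorm(n, 0, sig), nrow(image$pixels))
      sqrt((image$pixels + n1)^2 + n2^2)
    }
  })
  image
}
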