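# Digital model of the fillable-cylinder phantom.
#
# Phantom frame: origin at the midpoint of the cylinder axis, z along the
# cylinder axis, millimetres throughout. Placement error relative to the
# scanner frame is a rigid rotation ("tilt"), applied as intrinsic z-y-x
# rotations in degrees.

.tube_dims <- list(
  tube_15ml = list(outer_radius = 8.5, inner_radius = 7.0, length = 100),
  tube_5ml  = list(outer_radius = 6.1, inner_radius = 5.0, length = 45)
)

.plate_capacity <- list(
  cor_sag = c(tube_15ml = 15L, tube_5ml = 9L),
  axial   = c(tube_15ml = 18L, tube_5ml = 6L)
)

#' Describe one sample-tube slot
#'
#' @param center_xyz numeric length-3, position of the tube-axis midpoint in
#'   the phantom frame (mm).
#' @param axis numeric length-3 direction of the tube long axis (normalised
#'   internally).
#' @param material a [material_sample()].
#' @param size_class `"tube_15ml"` (15 ml conical tube) or `"tube_5ml"`
#'   (5 ml cryogenic tube); sets default radii and length.
#' @param outer_radius,inner_radius,length override the size-class defaults
#'   (mm). Conical tips are ignored: tubes are modelled as finite cylinders.
#' @return an object of class `vial_slot`.
#' @export
vial_slot <- function(center_xyz, axis, material,
                      size_class = c("tube_15ml", "tube_5ml"),
                      outer_radius = NULL, inner_radius = NULL, length = NULL) {
  size_class <- match.arg(size_class)
  dims <- .tube_dims[[size_class]]
  outer_radius <- outer_radius %||% dims$outer_radius
  inner_radius <- inner_radius %||% dims$inner_radius
  length <- length %||% dims$length
  if (!inherits(material, "material_sample"))
    stop_validation("material must be a material_sample")
  if (!(inner_radius > 0 && inner_radius < outer_radius))
    stop_validation("need 0 < inner_radius < outer_radius")
  if (length <= 0) stop_validation("tube length must be positive")
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop_validation("axis must be a nonzero vector")
  structure(list(center_xyz = as.numeric(center_xyz), axis = axis / nrm,
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 length = length, material = material,
                 size_class = size_class),
            class = "vial_slot")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a phantom geometry
#'
#' @param vials list of [vial_slot()] in along-row order (this order defines
#'   "consecutive" for the distortion metric).
#' @param background [material_sample()] of the liquid fill (water).
#' @param top_style `"flat"` (160 mm total length) or `"domed"` (214 mm).
#' @param plate_style `"cor_sag"`, `"axial"` or `"none"`.
#' @param outer_diameter,inner_diameter,body_length cylinder dimensions, mm.
#' @param tilt intrinsic z-y-x rotation of the phantom frame relative to the
#'   scanner frame, degrees.
#' @return an object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(vials, background,
                             top_style = c("flat", "domed"),
                             plate_style = c("cor_sag", "axial", "none"),
                             outer_diameter = 180, inner_diameter = 148,
                             body_length = 120, tilt = c(0, 0, 0)) {
  top_style <- match.arg(top_style)
  plate_style <- match.arg(plate_style)
  if (inner_diameter >= outer_diameter)
    stop_validation("inner_diameter must be smaller than outer_diameter")
  if (!inherits(background, "material_sample"))
    stop_validation("background must be a material_sample")
  if (length(tilt) != 3L || !is.numeric(tilt))
    stop_validation("tilt must be three angles (z, y, x) in degrees")
  if (length(vials) > 24L)
    stop_capacity(sprintf("phantom holds at most 24 samples, got %d",
                          length(vials)))
  total_length <- if (top_style == "domed") 214 else 160
  geom <- structure(
    list(outer_diameter = outer_diameter, inner_diameter = inner_diameter,
         body_length = body_length, top_style = top_style,
         total_length = total_length, plate_style = plate_style,
         vials = vials, background = background, tilt = as.numeric(tilt)),
    class = "phantom_geometry")
  .check_capacity(geom)
  .check_containment(geom)
  .check_overlap(geom)
  geom
}

.check_capacity <- function(geom) {
  if (geom$plate_style == "none") return(invisible(NULL))
  cap <- .plate_capacity[[geom$plate_style]]
  classes <- vapply(geom$vials, function(v) v$size_class, character(1))
  for (cl in names(cap)) {
    n <- sum(classes == cl)
    if (n > cap[[cl]])
      stop_capacity(sprintf(
        "%s plate holds at most %d %s tubes, got %d",
        geom$plate_style, cap[[cl]], cl, n))
  }
  invisible(NULL)
}

.check_containment <- function(geom) {
  r_in <- geom$inner_diameter / 2
  for (i in seq_along(geom$vials)) {
    v <- geom$vials[[i]]
    # distance of the tube axis (infinite line) from the cylinder axis (z)
    c2 <- v$center_xyz[1:2]
    a2 <- v$axis[1:2]
    n2 <- sum(a2^2)
    d <- if (n2 < 1e-12) sqrt(sum(c2^2)) else {
      t0 <- -sum(c2 * a2) / n2
      sqrt(sum((c2 + t0 * a2)^2))
    }
    if (d + v$outer_radius >= r_in)
      stop_geometry(sprintf(
        "vial %d (axis %.1f mm off-centre + radius %.1f mm) does not fit the %.1f mm inner radius",
        i, d, v$outer_radius, r_in))
  }
  invisible(NULL)
}

.check_overlap <- function(geom) {
  n <- length(geom$vials)
  if (n < 2L) return(invisible(NULL))
  ctr <- t(vapply(geom$vials, function(v) v$center_xyz, numeric(3)))
  rad <- vapply(geom$vials, function(v) v$outer_radius, numeric(1))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sqrt(sum((ctr[i, ] - ctr[j, ])^2)) < rad[i] + rad[j])
      stop_geometry(sprintf("vials %d and %d overlap", i, j))
  }
  invisible(NULL)
}

#' Build the default phantom layout
#'
#' Places sample tubes on a regular grid on the chosen plate. A layout short
#' enough to fit one row (the common case for the one-dimensional distortion
#' measurement) gives collinear, equally spaced vials; longer layouts wrap
#' into additional rows at `row_pitch`. List order is row-major along-row
#' order, which is the "consecutive" order for inter-vial distances.
#'
#' @param top_style `"flat"` or `"domed"`.
#' @param plate_style `"cor_sag"` (tube axes along y; coronal/sagittal slices
#'   show circular cross-sections) or `"axial"` (tube axes along z).
#' @param sample_layout character vector of material names resolved against
#'   `materials`, in along-row order.
#' @param spacing centre-to-centre spacing within a row, mm. Must exceed the
#'   tube outer diameter.
#' @param materials named list of [material_sample()]; defaults to
#'   [default_materials()].
#' @param size_class tube size class for every slot (recycled).
#' @param per_row maximum tubes per row before wrapping.
#' @param row_pitch spacing between rows, mm.
#' @param tilt placement rotation, degrees (z, y, x intrinsic).
#' @return a `phantom_geometry`.
#' @examples
#' geom <- build_default_phantom("flat", "cor_sag",
#'                               c("oil", "cu1", "cu2", "cu3"), spacing = 24)
#' @export
build_default_phantom <- function(top_style = "flat", plate_style = "cor_sag",
                                  sample_layout = c("oil", "cu1", "cu2", "cu3"),
                                  spacing = 24,
                                  materials = default_materials(),
                                  size_class = "tube_15ml",
                                  per_row = 5L, row_pitch = 30,
                                  tilt = c(0, 0, 0)) {
  if (plate_style == "none")
    stop_validation("a plate is required to hold samples")
  size_class <- rep_len(size_class, length(sample_layout))
  unknown <- setdiff(sample_layout, names(materials))
  if (length(unknown))
    stop_validation(paste0("unknown material(s): ",
                           paste(unknown, collapse = ", ")))
  r_out <- max(vapply(size_class, function(cl) .tube_dims[[cl]]$outer_radius,
                      numeric(1)))
  if (spacing <= 2 * r_out)
    stop_geometry(sprintf(
      "spacing %.1f mm must exceed the tube outer diameter %.1f mm",
      spacing, 2 * r_out))

  n <- length(sample_layout)
  idx <- seq_len(n) - 1L
  row <- idx %/% per_row
  col <- idx %% per_row
  n_in_row <- vapply(row, function(r) sum(row == r), integer(1))
  n_rows <- max(row) + 1L
  # centre each row on the plate axis; centre the row stack too
  x <- (col - (n_in_row - 1) / 2) * spacing
  off <- (row - (n_rows - 1) / 2) * row_pitch

  vials <- vector("list", n)
  for (i in seq_len(n)) {
    if (plate_style == "cor_sag") {
      center <- c(x[i], 0, off[i])   # plate in x-z plane, tubes along y
      axis <- c(0, 1, 0)
    } else {
      center <- c(x[i], off[i], 0)   # plate perpendicular to z, tubes along z
      axis <- c(0, 0, 1)
    }
    vials[[i]] <- vial_slot(center, axis, materials[[sample_layout[i]]],
                            size_class = size_class[i])
  }
  phantom_geometry(vials, background = materials$water,
                   top_style = top_style, plate_style = plate_style,
                   tilt = tilt)
}

# intrinsic z-y-x rotation matrix, angles in degrees
tilt_matrix <- function(tilt) {
  a <- tilt * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

.plane_frame <- function(plane) {
  switch(plane,
    axial    = list(n = c(0, 0, 1), u = c(1, 0, 0), v = c(0, 1, 0)),
    coronal  = list(n = c(0, 1, 0), u = c(1, 0, 0), v = c(0, 0, 1)),
    sagittal = list(n = c(1, 0, 0), u = c(0, 1, 0), v = c(0, 0, 1)),
    stop_validation(sprintf("unknown plane '%s'", plane)))
}

#' Ground-truth vial circles in an image plane
#'
#' Applies the phantom tilt, then orthogonally projects each vial's mid-tube
#' cross-section centre into the requested plane. A tilted tube traces an
#' ellipse; it is treated as a circle of the mean semi-axis radius. The
#' representative circle radius is the tube-wall mid-circle,
#' `(inner + outer) / 2`, matching what the edge-based detector fits. Vials
#' whose tube does not reach the plane are omitted; a plane that misses the
#' phantom entirely yields zero rows (not an error).
#'
#' @param geometry a `phantom_geometry`.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"` (scanner frame).
#' @param slice_offset plane offset along its normal, mm.
#' @return data frame with one row per intersected vial, in `geometry$vials`
#'   order: `vial`, `u_mm`, `v_mm` (in-plane centre), `radius_mm` (mid-wall),
#'   `inner_radius_mm`, `outer_radius_mm` (liquid and outer-wall circles),
#'   `material`.
#' @export
ground_truth_centers <- function(geometry, plane = "coronal",
                                 slice_offset = 0) {
  fr <- .plane_frame(plane)
  R <- tilt_matrix(geometry$tilt)
  empty <- data.frame(vial = integer(0), u_mm = numeric(0), v_mm = numeric(0),
                      radius_mm = numeric(0), inner_radius_mm = numeric(0),
                      outer_radius_mm = numeric(0),
                      material = character(0), stringsAsFactors = FALSE)
  bound <- sqrt((geometry$outer_diameter / 2)^2 + (geometry$total_length / 2)^2)
  if (abs(slice_offset) > bound) return(empty)

  rows <- lapply(seq_along(geometry$vials), function(i) {
    v <- geometry$vials[[i]]
    ctr <- as.numeric(R %*% v$center_xyz)
    ax <- as.numeric(R %*% v$axis)
    cosphi <- abs(sum(ax * fr$n))
    if (cosphi < 0.2) return(NULL)  # near-parallel: no circular cross-section
    # does the finite tube reach the plane?
    d1 <- sum((ctr + v$length / 2 * ax) * fr$n) - slice_offset
    d2 <- sum((ctr - v$length / 2 * ax) * fr$n) - slice_offset
    if (d1 * d2 > 0) return(NULL)
    p <- ctr - (sum(ctr * fr$n) - slice_offset) * fr$n
    stretch <- (1 + 1 / cosphi) / 2  # mean of ellipse semi-axes / radius
    data.frame(vial = i,
               u_mm = sum(p * fr$u), v_mm = sum(p * fr$v),
               radius_mm = (v$inner_radius + v$outer_radius) / 2 * stretch,
               inner_radius_mm = v$inner_radius * stretch,
               outer_radius_mm = v$outer_radius * stretch,
               material = v$material$name, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "plane") <- plane
  attr(out, "slice_offset") <- slice_offset
  out
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf(
    "<phantom_geometry> %s top (total %g mm), %s plate, %d vial(s), OD %g / ID %g mm, tilt (%g, %g, %g) deg\n",
    x$top_style, x$total_length, x$plate_style, length(x$vials),
    x$outer_diameter, x$inner_diameter, x$tilt[1], x$tilt[2], x$tilt[3]))
  for (i in seq_along(x$vials)) {
    v <- x$vials[[i]]
    cat(sprintf("  vial %d: %-6s %s at (%.1f, %.1f, %.1f) mm\n", i,
                v$material$name, v$size_class,
                v$center_xyz[1], v$center_xyz[2], v$center_xyz[3]))
  }
  invisible(x)
}
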