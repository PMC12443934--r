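# Geometry serialization: a flat, sectioned key/value text format.
# Units are always mm and seconds; keys carry unit suffixes.

#' Write a phantom geometry to a config file
#'
#' The format is a plain-text document with `[section]` headers and
#' `key = value` lines, sections `[body]`, `[top]`, `[plate]`,
#' `[materials]`, `[vials]`. It round-trips through
#' [read_geometry_config()].
#'
#' @param geometry a `phantom_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_config <- function(geometry, path) {
  g <- geometry
  lines <- c(
    "# phantomqa geometry config (units: mm, seconds)",
    "[body]",
    sprintf("outer_diameter_mm = %.6g", g$outer_diameter),
    sprintf("inner_diameter_mm = %.6g", g$inner_diameter),
    sprintf("body_length_mm = %.6g", g$body_length),
    sprintf("tilt_zyx_deg = %.10g %.10g %.10g", g$tilt[1], g$tilt[2], g$tilt[3]),
    sprintf("background_material = %s", g$background$name),
    "",
    "[top]",
    sprintf("style = %s", g$top_style),
    sprintf("total_length_mm = %.6g", g$total_length),
    "",
    "[plate]",
    sprintf("style = %s", g$plate_style),
    "",
    "[materials]")
  mats <- list()
  mats[[g$background$name]] <- g$background
  for (v in g$vials) mats[[v$material$name]] <- v$material
  for (m in mats) {
    lines <- c(lines, sprintf("%s = t1_s:%.10g t2_s:%.10g pd:%.10g",
                              m$name, m$t1, m$t2, m$pd))
  }
  lines <- c(lines, "", "[vials]")
  for (i in seq_along(g$vials)) {
    v <- g$vials[[i]]
    lines <- c(lines, sprintf(
      "vial%d = center_mm:%.10g,%.10g,%.10g axis:%.10g,%.10g,%.10g outer_radius_mm:%.10g inner_radius_mm:%.10g length_mm:%.10g material:%s size_class:%s",
      i, v$center_xyz[1], v$center_xyz[2], v$center_xyz[3],
      v$axis[1], v$axis[2], v$axis[3],
      v$outer_radius, v$inner_radius, v$length, v$material$name,
      v$size_class))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_io(sprintf("cannot open '%s' for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.parse_sections <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      cur <- gsub("^\\[|\\]$", "", ln)
      if (is.null(sections[[cur]])) sections[[cur]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) stop_format("key/value line before any [section]")
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      sections[[cur]][[key]] <- trimws(paste(kv[-1], collapse = "="))
    } else {
      stop_format(sprintf("unparseable config line: '%s'", ln))
    }
  }
  sections
}

.parse_tagged <- function(value) {
  # "t1_s:2.5 t2_s:2 pd:1" -> named character vector
  parts <- strsplit(trimws(value), "[[:space:]]+")[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

#' Read a phantom geometry from a config file
#'
#' @param path file written by [write_geometry_config()] (or hand-edited in
#'   the same format).
#' @return a `phantom_geometry`.
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("geometry config '%s' not found", path))
  sec <- .parse_sections(readLines(path, warn = FALSE))
  for (need in c("body", "top", "plate", "materials", "vials"))
    if (is.null(sec[[need]]))
      stop_format(sprintf("geometry config missing [%s] section", need))

  mats <- lapply(names(sec$materials), function(nm) {
    f <- .parse_tagged(sec$materials[[nm]])
    material_sample(nm, t1 = as.numeric(f[["t1_s"]]),
                    t2 = as.numeric(f[["t2_s"]]), pd = as.numeric(f[["pd"]]))
  })
  names(mats) <- names(sec$materials)

  vials <- lapply(sec$vials, function(val) {
    f <- .parse_tagged(val)
    num3 <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    mat <- mats[[f[["material"]]]]
    if (is.null(mat))
      stop_format(sprintf("vial references unknown material '%s'",
                          f[["material"]]))
    vial_slot(num3(f[["center_mm"]]), num3(f[["axis"]]), mat,
              size_class = f[["size_class"]],
              outer_radius = as.numeric(f[["outer_radius_mm"]]),
              inner_radius = as.numeric(f[["inner_radius_mm"]]),
              length = as.numeric(f[["length_mm"]]))
  })
  # preserve vial1, vial2, ... order
  ord <- order(as.integer(sub("^vial", "", names(sec$vials))))
  vials <- unname(vials[ord])

  bg <- mats[[sec$body$background_material]]
  if (is.null(bg)) stop_format("background material not found in [materials]")
  phantom_geometry(
    vials, background = bg,
    top_style = sec$top$style, plate_style = sec$plate$style,
    outer_diameter = as.numeric(sec$body$outer_diameter_mm),
    inner_diameter = as.numeric(sec$body$inner_diameter_mm),
    body_length = as.numeric(sec$body$body_length_mm),
    tilt = as.numeric(strsplit(sec$body$tilt_zyx_deg, "[[:space:]]+")[[1]]))
}
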