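#' Define a measurand material
#'
#' A material is described by its longitudinal and transverse relaxation times
#' and a relative proton density; these three numbers drive the spin-echo
#' signal equations used by the simulator.
#'
#' @param name short label, e.g. `"water"` or `"cu1"`.
#' @param t1 longitudinal relaxation time in seconds (> 0).
#' @param t2 transverse relaxation time in seconds (> 0, and `t2 <= t1`).
#' @param pd relative proton density in `[0, 1]`.
#' @param description free text (e.g. capsule count for the copper-zinc
#'   solutions).
#' @return an object of class `material_sample`.
#' @export
material_sample <- function(name, t1, t2, pd, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_validation("material name must be a non-empty string")
  for (v in list(t1 = t1, t2 = t2, pd = pd)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_validation("t1, t2, pd must be finite scalars")
  }
  if (t1 <= 0 || t2 <= 0) stop_validation("t1 and t2 must be positive")
  if (t2 > t1) stop_validation(sprintf("t2 (%g s) must not exceed t1 (%g s)", t2, t1))
  if (pd < 0 || pd > 1) stop_validation("pd must lie in [0, 1]")
  structure(list(name = name, t1 = t1, t2 = t2, pd = pd,
                 description = description),
            class = "material_sample")
}

#' Default material catalog for the phantom samples
#'
#' Water, olive oil, and three zinc-copper supplement solutions (one, two and
#' three dissolved capsules; 15/30/45 mg Zn with 2/4/6 mg Cu). Copper shortens
#' both T1 and T2, monotonically with concentration.
#'
#' The relaxation values are placeholders for the 64 mT regime, chosen so the
#' default renders reproduce the observed contrast behaviour (oil is the
#' brightest vial on T1-weighted inversion-recovery images; on T2-weighted
#' images water is brightest, the copper solutions darken with capsule count,
#' and oil is darkest). They are NOT reference relaxometry values -- none were
#' measured for these store-bought materials -- and every value can be
#' overridden via the geometry config.
#'
#' @return named list of [material_sample()] objects: `water`, `oil`, `cu1`,
#'   `cu2`, `cu3`.
#' @export
default_materials <- function() {
  list(
    water = material_sample("water", t1 = 2.50, t2 = 2.00, pd = 1.0,
                            description = "deionized water fill / sample"),
    oil   = material_sample("oil",   t1 = 0.15, t2 = 0.08, pd = 0.9,
                            description = "olive oil (approximate fat mimic)"),
    cu1   = material_sample("cu1",   t1 = 0.80, t2 = 0.30, pd = 1.0,
                            description = "1 capsule: 15 mg Zn + 2 mg Cu"),
    cu2   = material_sample("cu2",   t1 = 0.50, t2 = 0.18, pd = 1.0,
                            description = "2 capsules: 30 mg Zn + 4 mg Cu"),
    cu3   = material_sample("cu3",   t1 = 0.35, t2 = 0.12, pd = 1.0,
                            description = "3 capsules: 45 mg Zn + 6 mg Cu")
  )
}

#' @export
print.material_sample <- function(x, ...) {
  cat(sprintf("<material %s>  T1 = %g s  T2 = %g s  PD = %g  %s\n",
              x$name, x$t1, x$t2, x$pd, x$description))
  invisible(x)
}
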