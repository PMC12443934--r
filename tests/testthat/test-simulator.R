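test_that("IR-SE signal equation matches its closed form and limits", {
  seq <- sequence_params("ir_se", tr = 1.5, te = 0.006, ti = 0.3)
  # frozen from an independent evaluation of
  # 1000 * |1 - 2 e^{-0.3/0.5} + e^{-1.5/0.5}| * e^{-0.006/0.1}
  m <- material_sample("x", t1 = 0.5, t2 = 0.1, pd = 1)
  expect_equal(ir_se_signal(m, seq), 45.0504401792, tolerance = 1e-10)

  # t1 -> 0+ with te = 0: all exponentials vanish, intensity -> pd
  seq0 <- sequence_params("ir_se", tr = 1.5, te = 0, ti = 0.3)
  m0 <- material_sample("x", t1 = 1e-4, t2 = 1e-5, pd = 0.8)
  expect_equal(ir_se_signal(m0, seq0), 0.8 * 1000, tolerance = 1e-9)

  # null point: ti = t1 ln 2 with tr >> t1
  t1 <- 0.4
  seqn <- sequence_params("ir_se", tr = 20 * t1, te = 0, ti = t1 * log(2))
  mn <- material_sample("x", t1 = t1, t2 = 0.2, pd = 1)
  expect_lt(ir_se_signal(mn, seqn), 1e-6 * 1000)

  expect_error(ir_se_signal(m, sequence_params("se", tr = 2, te = 0.231)),
               class = "phantomqa_usage_error")
})

test_that("SE signal equation matches its closed form and limits", {
  # te = 0, tr >= 20 t1: full recovery, no decay -> pd
  m <- material_sample("x", t1 = 0.1, t2 = 0.05, pd = 0.7)
  expect_equal(se_signal(m, sequence_params("se", tr = 2, te = 0)), 700,
               tolerance = 1e-8)
  # te = 0 removes the T2 term (the t2 -> Inf limit): pd (1 - e^{-1})
  m2 <- material_sample("x", t1 = 2, t2 = 2, pd = 1)
  expect_equal(se_signal(m2, sequence_params("se", tr = 2, te = 0)),
               632.120558829, tolerance = 1e-10)
  expect_error(se_signal(m, sequence_params("ir_se", tr = 1.5, te = 0.006,
                                            ti = 0.3)),
               class = "phantomqa_usage_error")
})

test_that("default materials give the documented contrast orderings", {
  mats <- default_materials()
  t2w <- sequence_preset("t2w_coronal")
  s <- vapply(mats, se_signal, numeric(1), seq = t2w)
  expect_true(s[["water"]] > s[["cu1"]] && s[["cu1"]] > s[["cu2"]] &&
              s[["cu2"]] > s[["cu3"]] && s[["cu3"]] > s[["oil"]])
  t1w <- sequence_preset("t1w_coronal")
  s1 <- vapply(mats, ir_se_signal, numeric(1), seq = t1w)
  expect_equal(names(which.max(s1)), "oil")
  expect_gt(s1[["oil"]], s1[["water"]])  # oil contrasts against the fill
})

test_that("pixel grids follow round(fov / resolution) for all presets", {
  shapes <- list(
    t1w_coronal = c(112, 112),  # 180 / 1.6 per axis
    t2w_coronal = c(120, 120),  # 180 / 1.5
    t1w_axial   = c(138, 112),  # rows: 220 / 1.6, cols: 180 / 1.6
    t2w_axial   = c(147, 120))  # rows: 220 / 1.5, cols: 180 / 1.5
  axial_geom <- build_default_phantom("flat", "axial",
                                      c("oil", "cu1", "cu2", "cu3"),
                                      spacing = 24)
  for (nm in names(shapes)) {
    seq <- sequence_preset(nm)
    geom <- if (seq$plane == "axial") axial_geom else default_row_geometry()
    img <- render_slice(geom, seq)
    expect_equal(dim(img$pixels), shapes[[nm]], info = nm)
    expect_equal(nrow(img$pixels), round(seq$fov_xy[2] / seq$resolution_xy[2]))
    expect_equal(ncol(img$pixels), round(seq$fov_xy[1] / seq$resolution_xy[1]))
  }
})

test_that("noise-free render hits the closed-form signal at vial centres", {
  for (img in list(noise_free_t1w(), noise_free_t2w())) {
    gt <- img$meta$ground_truth
    mats <- default_materials()
    seq <- do.call(sequence_params,
                   img$meta$sequence[c("family", "tr", "te", "ti", "averages",
                                       "fov_xy", "resolution_xy",
                                       "slice_thickness", "plane")])
    for (i in seq_len(nrow(gt))) {
      got <- img$pixels[round(gt$row_px[i]) + 1L, round(gt$col_px[i]) + 1L]
      want <- if (seq$family == "ir_se") ir_se_signal(mats[[gt$material[i]]], seq)
              else se_signal(mats[[gt$material[i]]], seq)
      expect_equal(got, want, tolerance = 0.01)
    }
  }
})

test_that("ground-truth separations come out in exact pixel units", {
  img <- noise_free_t2w()  # 1.5 mm pixels, 24 mm spacing
  gt <- img$meta$ground_truth
  expect_equal(diff(gt$col_px), rep(16, 3))
  expect_equal(diff(gt$row_px), rep(0, 3))
})

test_that("affine scaling of world coordinates scales the ground truth", {
  s <- 1.05
  img <- render_slice(default_row_geometry(), sequence_preset("t2w_coronal"),
                      distortion = distortion_field("affine", A = s * diag(2)))
  expect_equal(diff(img$meta$ground_truth$u_mm), rep(24 * s, 3),
               tolerance = 1e-12)
})

test_that("radial distortion ground truth matches the forward map", {
  k <- 1e-5
  img <- render_slice(default_row_geometry(), sequence_preset("t2w_coronal"),
                      distortion = distortion_field("radial", k = k))
  gt <- img$meta$ground_truth
  r0 <- c(-36, -12, 12, 36)
  expect_equal(gt$u_mm, r0 * (1 + k * r0^2), tolerance = 1e-9)
})

test_that("noise application is deterministic and sigma = 0 is a no-op", {
  img <- noise_free_t1w()
  expect_identical(add_noise(img, noise_model("rician", 0, 1))$pixels,
                   img$pixels)
  a <- add_noise(img, noise_model("rician", 5, 99), averages = 24)
  b <- add_noise(img, noise_model("rician", 5, 99), averages = 24)
  c <- add_noise(img, noise_model("rician", 5, 100), averages = 24)
  expect_identical(a$pixels, b$pixels)
  expect_false(identical(a$pixels, c$pixels))
  # the caller's RNG stream is not consumed
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(add_noise(img, noise_model("rician", 5, 7)))
  expect_identical(runif(1), x1)
  expect_error(noise_model("rician", -1), class = "phantomqa_validation_error")
})

test_that("Rician noise on a zero image is Rayleigh distributed", {
  sigma <- 3
  z <- slice_image(matrix(0, 320, 320), c(1, 1))  # > 1e5 pixels
  out <- add_noise(z, noise_model("rician", sigma, 2024))
  # Rayleigh mean sigma sqrt(pi/2) = 3.7599...; MC standard error ~ 0.006
  expect_equal(mean(out$pixels), sigma * sqrt(pi / 2), tolerance = 0.01)
  expect_equal(sd(out$pixels), sigma * sqrt(2 - pi / 2), tolerance = 0.02)
})

test_that("gaussian noise is truncated at zero", {
  z <- slice_image(matrix(0, 100, 100), c(1, 1))
  out <- add_noise(z, noise_model("gaussian", 4, 3))
  expect_true(all(out$pixels >= 0))
  expect_gt(mean(out$pixels == 0), 0.3)  # roughly half the mass truncates
})
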