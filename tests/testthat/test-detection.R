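test_that("threshold_edges marks a closed ring around every vial", {
  img <- noise_free_t1w()
  edge <- threshold_edges(img)
  gt <- img$meta$ground_truth
  sp <- mean(img$spacing_xy)
  for (i in seq_len(nrow(gt))) {
    # walk 64 rays from the centre: each must cross a marked pixel near the
    # wall radius, i.e. the ring is closed
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    hit <- vapply(th, function(a) {
      rr <- seq(gt$inner_radius_mm[i] - 2, gt$outer_radius_mm[i] + 2,
                by = sp / 2) / sp
      any(vapply(rr, function(r) {
        cc <- round(gt$col_px[i] + r * cos(a)) + 1L
        rw <- round(gt$row_px[i] + r * sin(a)) + 1L
        edge[rw, cc]
      }, logical(1)))
    }, logical(1))
    expect_true(all(hit))
  }
})

test_that("degenerate inputs follow the documented contracts", {
  zero <- slice_image(matrix(0, 32, 32), c(1.5, 1.5))
  expect_error(threshold_edges(zero), class = "phantomqa_detection_error")
  # fixed threshold at 0 on a positive image: everything is foreground, so
  # there are no edges and downstream detection reports zero candidates
  pos <- slice_image(matrix(runif(32 * 32) + 1, 32), c(1.5, 1.5))
  params <- detection_params(threshold_method = "fixed", fixed_threshold = 0)
  expect_equal(nrow(detect_vials(pos, params)), 0L)
})

test_that("noise-free detection is sub-pixel across spacings and resolutions", {
  for (spacing in c(20, 24, 30)) {
    for (preset in c("t1w_coronal", "t2w_coronal")) {
      geom <- build_default_phantom("flat", "cor_sag",
                                    c("oil", "cu1", "cu2", "cu3"),
                                    spacing = spacing)
      img <- render_slice(geom, sequence_preset(preset))
      rois <- detect_vials(img, detection_params(expected_count = 4))
      gt <- img$meta$ground_truth
      err <- sqrt((rois$col_px - gt$col_px)^2 + (rois$row_px - gt$row_px)^2)
      expect_true(all(err < 0.5),
                  info = sprintf("%s spacing %d: max err %.3f px",
                                 preset, spacing, max(err)))
      # radius within 1 pixel of the wall mid-circle
      sp <- mean(img$spacing_xy)
      expect_true(all(abs(rois$radius_mm - gt$radius_mm) < sp),
                  info = sprintf("%s spacing %d", preset, spacing))
    }
  }
})

test_that("detection survives the T1w noise regime over several seeds", {
  img0 <- noise_free_t1w()
  gt <- img0$meta$ground_truth
  for (seed in 1:5) {
    img <- add_noise(img0, noise_model("rician", 10, seed), averages = 24)
    rois <- detect_vials(img, detection_params(expected_count = 4))
    err <- sqrt((rois$col_px - gt$col_px)^2 + (rois$row_px - gt$row_px)^2)
    expect_true(all(err < 0.5), info = sprintf("seed %d", seed))
  }
})

test_that("the lsq_boundary fit method also recovers the row", {
  img <- noise_free_t1w()
  rois <- detect_vials(img, detection_params(expected_count = 4,
                                             fit_method = "lsq_boundary"))
  gt <- img$meta$ground_truth
  err <- sqrt((rois$col_px - gt$col_px)^2 + (rois$row_px - gt$row_px)^2)
  expect_true(all(err < 0.5))
})

test_that("a shortfall against expected_count raises a detection error", {
  geom <- build_default_phantom("flat", "cor_sag", c("oil", "cu1", "cu3"),
                                spacing = 24)
  img <- render_slice(geom, sequence_preset("t1w_coronal"))
  err <- expect_error(detect_vials(img, detection_params(expected_count = 4)),
                      class = "phantomqa_detection_error")
  expect_match(conditionMessage(err), "found 3")
})

test_that("detection is equivariant under a 90-degree image rotation", {
  img <- noise_free_t2w()
  rois <- detect_vials(img, detection_params(expected_count = 4))
  rot <- img
  rot$pixels <- t(img$pixels)[ncol(img$pixels):1, ]  # rotate 90 deg CCW
  rot$origin_world <- -(c(ncol(rot$pixels), nrow(rot$pixels)) - 1) / 2 *
    rot$spacing_xy
  rois_rot <- detect_vials(rot, detection_params(expected_count = 4))
  n <- nrow(img$pixels)
  # pixel (c, r) maps to (r, n - 1 - c) under this rotation
  mapped_col <- rois$row_px
  mapped_row <- (n - 1) - rois$col_px
  ord <- order(mapped_row)  # rotated row runs vertically
  err <- sqrt((sort(rois_rot$col_px) - sort(mapped_col))^2 +
              (sort(rois_rot$row_px) - sort(mapped_row))^2)
  expect_true(all(err < 0.5))
})

test_that("order_vials sorts along the principal axis with stable ties", {
  df <- data.frame(x_mm = c(0, 48, 24, 72), y_mm = 0,
                   radius_mm = 7.75, label = NA, fit_score = 1)
  expect_equal(order_vials(df)$x_mm, c(0, 24, 48, 72))
  one <- df[1, ]
  expect_equal(nrow(order_vials(one)), 1L)
  # vertical row: principal axis is vertical
  vert <- data.frame(x_mm = 0, y_mm = c(30, -10, 10), radius_mm = 7.75,
                     label = NA, fit_score = 1)
  expect_equal(order_vials(vert)$y_mm, c(-10, 10, 30))
})

test_that("detection success is monotone in noise and perfect at sigma 0", {
  img0 <- noise_free_t1w()
  success_rate <- function(sigma, seeds = 1:6) {
    mean(vapply(seeds, function(s) {
      img <- add_noise(img0, noise_model("rician", sigma, s), averages = 24)
      ok <- tryCatch({
        rois <- detect_vials(img, detection_params(expected_count = 4))
        gt <- img0$meta$ground_truth
        all(sqrt((rois$col_px - gt$col_px)^2 +
                 (rois$row_px - gt$row_px)^2) < 1)
      }, error = function(e) FALSE)
      as.numeric(ok)
    }, numeric(1)))
  }
  rates <- vapply(c(0, 20, 400), success_rate, numeric(1))
  expect_equal(rates[1], 1)
  expect_true(all(diff(rates) <= 0))
})
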