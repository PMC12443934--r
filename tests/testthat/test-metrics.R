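test_that("inter-vial distances are consecutive Euclidean distances", {
  # worked example: the T2-weighted flat-top row
  ctrs <- cbind(c(0, 24, 46.5, 72), 0)
  expect_equal(inter_vial_distances(ctrs), c(24.0, 22.5, 25.5))
  expect_equal(inter_vial_distances(cbind(c(0, 0), c(0, 0))), 0)
  expect_equal(inter_vial_distances(cbind(c(0, 3), c(0, 4))), 5)
  expect_error(inter_vial_distances(cbind(1, 1)),
               class = "phantomqa_insufficient_data_error")
})

test_that("average distance is the arithmetic mean", {
  expect_equal(round(average_distance(c(24.0, 22.5, 25.5)), 1), 24.0)
  expect_equal(round(average_distance(c(24.1, 24.1, 25.6)), 1), 24.6)
  expect_equal(average_distance(rep(17.3, 5)), 17.3)
  expect_error(average_distance(numeric(0)),
               class = "phantomqa_insufficient_data_error")
  # mean idempotence under concatenated copies
  d <- c(24.0, 22.5, 25.5)
  for (k in c(2, 5)) {
    expect_equal(average_distance(rep(d, k)), average_distance(d))
  }
})

test_that("compare_scans reproduces the flat/domed comparison statistics", {
  rep_t1_flat <- qa_report(c(24.0, 24.0, 24.0), pixel_spacing = 1.6)
  rep_t2_flat <- qa_report(c(24.0, 22.5, 25.5), pixel_spacing = 1.5)
  flat <- compare_scans(rep_t1_flat, rep_t2_flat)
  expect_equal(flat$difference, 0)
  expect_equal(flat$relative_percent, 0)
  expect_true(flat$within_pixel)

  rep_t1_domed <- qa_report(c(24.1, 24.1, 25.6), pixel_spacing = 1.6)
  rep_t2_domed <- qa_report(c(24.0, 25.5, 24.0), pixel_spacing = 1.5)
  domed <- compare_scans(rep_t1_domed, rep_t2_domed)
  expect_equal(domed$difference, 0.1, tolerance = 1e-9)
  expect_lt(domed$relative_percent, 1)  # the within-1-percent claim
  expect_true(domed$within_pixel)      # 0.1 mm <= 1.5 mm

  self <- compare_scans(rep_t1_flat, rep_t1_flat)
  expect_equal(self$difference, 0)
  expect_true(self$within_pixel)
})

make_region_image <- function() {
  # 20 x 20 image: signal block constant, noise strip with known sd
  px <- matrix(0, 20, 20)
  px[3:7, 3:7] <- 10
  px[15, 3:5] <- c(0, 2, 4)  # sample sd exactly 2, mean 2
  slice_image(px, c(1, 1))
}

test_that("SNR and CNR follow their defining formulas", {
  img <- make_region_image()
  sig <- region_spec("signal", c(2, 2), c(5, 5))
  nz <- region_spec("noise", c(2, 14), c(3, 1))
  expect_equal(as.numeric(compute_snr(img, sig, nz)), 5)
  expect_equal(compute_cnr(img, sig, nz), (10 - 2) / 2)

  # signal region constant 0 -> SNR 0
  sig0 <- region_spec("signal", c(10, 10), c(5, 5))
  expect_equal(as.numeric(compute_snr(img, sig0, nz)), 0)

  # mean signal 12 gives the printed CNR example (12 - 2) / 2 = 5
  img2 <- img; img2$pixels[3:7, 3:7] <- 12
  expect_equal(compute_cnr(img2, sig, nz), 5)

  # zero noise sd is an error, not infinity
  flat <- img; flat$pixels[15, 3:5] <- 2
  expect_error(compute_snr(flat, sig, nz),
               class = "phantomqa_validation_error")
})

test_that("CNR equals zero when signal mean equals noise mean, and CNR < SNR", {
  img <- make_region_image()
  img$pixels[3:7, 3:7] <- 2  # equal to the noise mean
  sig <- region_spec("signal", c(2, 2), c(5, 5))
  nz <- region_spec("noise", c(2, 14), c(3, 1))
  expect_identical(compute_cnr(img, sig, nz), 0)
  img$pixels[3:7, 3:7] <- 7
  expect_lt(compute_cnr(img, sig, nz),
            as.numeric(compute_snr(img, sig, nz)))
})

test_that("SNR/CNR are scale invariant and respond to shifts asymmetrically", {
  img <- add_noise(noise_free_t1w(), noise_model("rician", 10, 5),
                   averages = 24)
  rois <- detect_vials(img, detection_params(expected_count = 4))
  reg <- auto_place_regions(img, rois, "t1w")
  snr1 <- as.numeric(compute_snr(img, reg$signal, reg$noise))
  cnr1 <- compute_cnr(img, reg$signal, reg$noise)
  for (c in c(0.5, 3)) {
    scaled <- img; scaled$pixels <- img$pixels * c
    expect_equal(as.numeric(compute_snr(scaled, reg$signal, reg$noise)),
                 snr1, tolerance = 1e-9)
    expect_equal(compute_cnr(scaled, reg$signal, reg$noise), cnr1,
                 tolerance = 1e-9)
  }
  # adding a constant to the noise pixels leaves SNR alone (sd is
  # shift-invariant) but not CNR; adding to the signal region changes SNR
  shifted <- img
  for (r in reg$noise)
    shifted$pixels[r$top_left[2] + 1:10, r$top_left[1] + 1:10] <-
      shifted$pixels[r$top_left[2] + 1:10, r$top_left[1] + 1:10] + 50
  expect_equal(as.numeric(compute_snr(shifted, reg$signal, reg$noise)), snr1,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(compute_cnr(shifted, reg$signal, reg$noise),
                                cnr1)))
  bumped <- img
  s <- reg$signal
  bumped$pixels[s$top_left[2] + 1:5, s$top_left[1] + 1:5] <-
    bumped$pixels[s$top_left[2] + 1:5, s$top_left[1] + 1:5] + 50
  expect_gt(as.numeric(compute_snr(bumped, reg$signal, reg$noise)), snr1)
})

test_that("auto placement puts regions where the protocol says", {
  # T1w: signal region inside the brightest (oil) vial
  img <- noise_free_t1w()
  rois <- detect_vials(img, detection_params(expected_count = 4))
  reg <- auto_place_regions(img, rois, "t1w")
  gt <- img$meta$ground_truth
  oil <- gt[gt$material == "oil", ]
  ctr <- reg$signal$top_left + 2
  expect_lt(sqrt((ctr[1] - oil$col_px)^2 + (ctr[2] - oil$row_px)^2),
            oil$inner_radius_mm / mean(img$spacing_xy))

  # T2w: signal region in the fill, outside every vial disk
  img2 <- noise_free_t2w()
  rois2 <- detect_vials(img2, detection_params(expected_count = 4))
  reg2 <- auto_place_regions(img2, rois2, "t2w")
  gt2 <- img2$meta$ground_truth
  ctr2 <- reg2$signal$top_left + 2
  for (i in seq_len(nrow(gt2))) {
    expect_gt(sqrt((ctr2[1] - gt2$col_px[i])^2 + (ctr2[2] - gt2$row_px[i])^2),
              gt2$outer_radius_mm[i] / mean(img2$spacing_xy))
  }
  # inside the inner cylinder: world position within the inner radius
  w <- pixel_to_world(img2, ctr2[1], ctr2[2])
  expect_lt(abs(w[1]), 74)

  # noise regions are clear of the phantom: pure background statistics
  for (r in reg2$noise) {
    vals <- img2$pixels[r$top_left[2] + 1:10, r$top_left[1] + 1:10]
    expect_true(all(vals == 0))
  }
})

test_that("an image with no clear background refuses auto placement", {
  px <- matrix(1000, 40, 40) + matrix(runif(1600), 40)
  img <- slice_image(px, c(1.5, 1.5))
  expect_error(auto_place_regions(img, NULL, "t2w"),
               class = "phantomqa_placement_error")
})

test_that("qa_report enforces its invariants", {
  r <- qa_report(c(24, 25), snr = 300, cnr = 295, pixel_spacing = 1.6)
  expect_equal(r$average_distance, mean(r$distances))
  expect_error(qa_report(numeric(0), pixel_spacing = 1.6),
               class = "phantomqa_insufficient_data_error")
  expect_error(qa_report(c(24, -2), pixel_spacing = 1.6),
               class = "phantomqa_validation_error")
})
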