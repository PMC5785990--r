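test_that("segmentation recovers the exact band on a clean phantom", {
  b <- make_phantom(quick_geometry(), clean_optics(), in_focus(), seed = 1)
  s <- segment_retina(b$pixels)
  expect_true(s$success)
  iou <- sum(s$tissue_mask & b$truth$tissue) /
    sum(s$tissue_mask | b$truth$tissue)
  expect_equal(iou, 1)
})

test_that("segmentation stays accurate under noise", {
  b <- make_phantom(quick_geometry(), phantom_optics(base_noise_sd = 0.03),
                    acquisition_setting("middle", 1, 0), seed = 7)
  s <- segment_retina(b$pixels)
  expect_true(s$success)
  iou <- sum(s$tissue_mask & b$truth$tissue) /
    sum(s$tissue_mask | b$truth$tissue)
  expect_gte(iou, 0.90)
})

test_that("degenerate images fail segmentation with a reason", {
  s0 <- segment_retina(matrix(0, 50, 80))
  expect_false(s0$success)
  expect_match(s0$failure_reason, "no tissue")
  s1 <- segment_retina(matrix(0.5, 50, 80))
  expect_false(s1$success)
  m0 <- analyse_bscan(matrix(0, 50, 80))
  expect_equal(m0$status, "failed")
})

test_that("RPE band extraction follows the lower tissue edge", {
  b <- make_phantom(quick_geometry(), clean_optics(), in_focus(), seed = 1)
  s <- segment_retina(b$pixels)
  cfg <- seg_config(rpe_band_thickness = 8)  # true RPE thickness
  rpe <- locate_rpe(s, cfg)
  expect_identical(rpe, b$truth$rpe)
  expect_true(all(s$tissue_mask[rpe]))
  # band thickness saturating at the tissue thickness gives the whole mask
  rpe_all <- locate_rpe(s, seg_config(rpe_band_thickness = 1000))
  expect_identical(rpe_all, s$tissue_mask)
})

test_that("vitreous patch respects margin, crop and disjointness", {
  b <- make_phantom(quick_geometry(), clean_optics(), in_focus(), seed = 1)
  s <- segment_retina(b$pixels)
  cfg <- seg_config(patch_margin = 10, lateral_crop_fraction = 0.6)
  p <- build_vitreous_patch(b$pixels, s, cfg)
  expect_true(p$success)
  expect_false(any(p$mask & s$tissue_mask))
  for (j in which(colSums(p$mask) > 0)) {
    top_patch <- max(which(p$mask[, j]))
    expect_lte(top_patch, s$inner_boundary[j] - 1 - 10)
  }
  # crop arithmetic: fraction 0.6 of 500 columns keeps columns 101..400
  wide <- matrix(0.01, 60, 500); wide[40:55, ] <- 0.9
  sw <- segment_retina(wide, seg_config(opening_radius = 3))
  pw <- build_vitreous_patch(wide, sw,
                             seg_config(lateral_crop_fraction = 0.6,
                                        patch_margin = 2,
                                        min_patch_pixels = 10))
  cols <- which(colSums(pw$mask) > 0)
  expect_equal(range(cols), c(101, 400))
})

test_that("a retina at the image top leaves no vitreous and fails", {
  g <- phantom_geometry(retina_top_row = 0, fovea_depth = 0)
  b <- make_phantom(g, clean_optics(), in_focus(), seed = 1)
  m <- analyse_bscan(b)
  expect_equal(m$status, "failed")
  expect_match(m$reason, "patch")
})

test_that("the VRI is the exact patch/RPE mean ratio", {
  b <- make_phantom(quick_geometry(),
                    clean_optics(vitreous_mean = 10 / 255,
                                 rpe_mean = 200 / 255),
                    in_focus(), seed = 1)
  m <- compute_vri(b$pixels, b$truth$rpe, b$truth$vitreous)
  expect_equal(m$vri, 0.05, tolerance = 1e-15)
  # identical intensities in both regions give a ratio of exactly 1
  flat <- matrix(0.3, 40, 40)
  m1 <- compute_vri(flat, flat > 0, flat > 0)
  expect_identical(m1$vri, 1)
  # zero RPE signal is a failure, not a division
  z <- matrix(0, 40, 40); z[30:35, ] <- 0
  mz <- compute_vri(z, rbind(matrix(FALSE, 30, 40), matrix(TRUE, 10, 40)),
                    rbind(matrix(TRUE, 10, 40), matrix(FALSE, 30, 40)))
  expect_equal(mz$status, "failed")
  expect_match(mz$reason, "zero RPE")
})

test_that("measured VRI equals the truth ratio on noise-free phantoms", {
  for (art in c(6, 100)) {
    b <- make_phantom(quick_geometry(), clean_optics(),
                      in_focus(art), seed = 1)
    m <- analyse_bscan(b)
    expect_equal(m$status, "ok")
    expect_lt(abs(m$vri - b$truth$vri), 1e-12)
  }
})

test_that("the VRI is invariant to global intensity scaling", {
  b <- make_phantom(quick_geometry(), clean_optics(), in_focus(), seed = 1)
  ref <- analyse_bscan(b$pixels)$vri
  for (c in c(0.25, 0.5, 0.9))
    expect_equal(analyse_bscan(b$pixels * c)$vri, ref, tolerance = 1e-12)
  bn <- make_phantom(quick_geometry(), phantom_optics(), in_focus(),
                     seed = 2)
  expect_equal(analyse_bscan(bn$pixels * 0.5)$vri,
               analyse_bscan(bn$pixels)$vri, tolerance = 0.01)
})

test_that("batch analysis conserves records and parses filenames", {
  g <- quick_geometry()
  scans <- lapply(1:4, function(i)
    make_phantom(g, phantom_optics(), in_focus(), seed = i, subject = i))
  tab <- analyse_batch(scans)
  expect_equal(nrow(tab), 4L)
  expect_true(all(!tab$failed))

  dir <- withr::local_tempdir()
  write_bscan(scans[[1]], file.path(dir, "sub03_set1_rep2_sec5.png"))
  t2 <- measure_directory(dir)
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$subject, 3L)
  expect_equal(t2$repetition, 2L)
  expect_equal(t2$section, 5L)
  expect_equal(t2$setting, "middle_art100_f0")
})
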