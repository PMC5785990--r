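test_that("zero-noise zero-haze phantom renders vitreous at background", {
  o <- phantom_optics(vitreous_mean = 0.02, background_mean = 0.02,
                      base_noise_sd = 0)
  b <- make_phantom(quick_geometry(), o, in_focus(), seed = 1)
  expect_true(all(b$pixels[b$truth$vitreous] == 0.02))
})

test_that("noise-free region means equal the configured intensities", {
  o <- clean_optics(vitreous_mean = 10 / 255, rpe_mean = 200 / 255)
  b <- make_phantom(quick_geometry(), o, in_focus(), seed = 1)
  expect_identical(mean(b$pixels[b$truth$vitreous]), 10 / 255)
  expect_identical(mean(b$pixels[b$truth$rpe]), 200 / 255)
  expect_equal(b$truth$vri, 0.05, tolerance = 1e-15)
  expect_true(all(b$pixels >= 0 & b$pixels <= 1))
})

test_that("vitreous noise sd scales as 1/sqrt(ART)", {
  g <- quick_geometry()
  o <- phantom_optics(base_noise_sd = 0.03)
  b6 <- make_phantom(g, o, acquisition_setting("middle", 6, 0), seed = 42)
  b100 <- make_phantom(g, o, acquisition_setting("middle", 100, 0),
                       seed = 42)
  expect_gt(sum(b6$truth$vitreous), 1e4)
  sd6 <- sd(b6$pixels[b6$truth$vitreous])
  sd100 <- sd(b100$pixels[b100$truth$vitreous])
  expect_equal(sd6 / sd100, sqrt(100 / 6), tolerance = 0.05)
})

test_that("focus gain raises the vitreous signal and blur smooths edges", {
  g <- quick_geometry()
  o <- clean_optics()
  b0 <- make_phantom(g, o, in_focus(), seed = 1)
  b5 <- make_phantom(g, o, acquisition_setting("middle", 100, 5), seed = 1)
  expect_gt(b5$truth$vitreous_mean, b0$truth$vitreous_mean)
  expect_gt(b5$truth$vri, b0$truth$vri)
})

test_that("bottom positioning moves the band down and dims the RPE", {
  g <- quick_geometry()
  o <- clean_optics()
  mid <- make_phantom(g, o, in_focus(), seed = 1)
  bot <- make_phantom(g, o, acquisition_setting("bottom", 100, 0), seed = 1)
  row_of <- function(m) max(which(rowSums(m) > 0))
  expect_gt(row_of(bot$truth$rpe), row_of(mid$truth$rpe))
  expect_lt(bot$truth$rpe_mean, mid$truth$rpe_mean)
  expect_gt(bot$truth$vri, mid$truth$vri)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_geometry(height = 100, retina_top_row = 80,
                                retina_thickness = 40, rpe_thickness = 8),
               "beyond the image")
  expect_error(phantom_geometry(fovea_depth = 60, retina_thickness = 40),
               "fovea_depth")
  expect_error(phantom_optics(vitreous_mean = 0.9, rpe_mean = 0.5))
  expect_error(phantom_optics(focus_gain_map = c("0" = 1, "5" = 0.5)),
               ">= 1")
})

test_that("phantom noise is seeded and does not disturb the global RNG", {
  g <- quick_geometry()
  o <- phantom_optics()
  b1 <- make_phantom(g, o, in_focus(), seed = 9)
  b2 <- make_phantom(g, o, in_focus(), seed = 9)
  expect_identical(b1$pixels, b2$pixels)
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_phantom(g, o, in_focus(), seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("B-scans survive an 8-bit PNG round trip", {
  b <- make_phantom(quick_geometry(), phantom_optics(), in_focus(),
                    seed = 3)
  path <- file.path(withr::local_tempdir(), "sub01_set1_rep1_sec1.png")
  write_bscan(b, path)
  r <- read_bscan(path)
  expect_equal(dim(r$pixels), dim(b$pixels))
  expect_lt(max(abs(r$pixels - b$pixels)), 1 / 255)
})
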