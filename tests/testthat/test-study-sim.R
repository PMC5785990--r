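test_that("degenerate variance gives every slot its setting mean exactly", {
  d <- enumerate_protocol(3, 2, 4)
  s <- generate_study(d, vc = variance_components(0, 0, 0), seed = 5)
  mu <- reference_setting_means()
  expect_identical(s$vri, unname(mu[s$setting]))
  expect_equal(nrow(s), nrow(d))
})

test_that("simulated studies are reproducible and slot-stable", {
  d <- enumerate_protocol(4, 3, 7)
  s1 <- generate_study(d, seed = 11)
  s2 <- generate_study(d, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(s1$vri, generate_study(d, seed = 12)$vri))
  # per-slot streams: subsetting the design leaves shared slots unchanged
  sub <- generate_study(d[d$subject <= 2, ], seed = 11)
  expect_identical(sub$vri, s1$vri[s1$subject <= 2])
})

test_that("within-scan spread of a section-only simulation matches its sd", {
  d <- protocol_arm(enumerate_protocol(15, 3, 7), "art")
  s <- generate_study(d, vc = variance_components(0, 0, 0.010), seed = 8)
  r <- compute_level_residuals(s, "within_scan")
  scans <- !duplicated(paste(r$subject, r$setting, r$repetition))
  pooled_sd <- sqrt(sum(r$squared_residual) / sum(r$n_group[scans] - 1))
  expect_gte(pooled_sd, 0.008)
  expect_lte(pooled_sd, 0.012)
})

test_that("a missing setting mean is reported by name", {
  d <- enumerate_protocol(1, 1, 1)
  mu <- reference_setting_means()
  expect_error(
    generate_study(d, mu[names(mu) != "bottom_art100_f0"]),
    "bottom_art100_f0")
})

test_that("failure injection is seeded, bounded and conservative", {
  d <- protocol_arm(enumerate_protocol(15, 3, 7), "focus")
  s <- generate_study(d, seed = 2)
  expect_identical(inject_failures(s, c(middle_art100_f0 = 0), seed = 1), s)

  all_failed <- inject_failures(s, setNames(1, "middle_art100_f+10"),
                                seed = 1)
  hit <- all_failed$setting == "middle_art100_f+10"
  expect_true(all(all_failed$failed[hit]))
  expect_true(all(is.na(all_failed$vri[hit])))
  expect_false(any(all_failed$failed[!hit]))

  # binomial accounting: p = 0.32 on 1575 slots stays within 3 sd of 504
  p <- setNames(rep(0.32, 5), unique(s$setting))
  f <- inject_failures(s, p, seed = 3)
  expect_lt(abs(sum(f$failed) - 0.32 * 1575),
            3 * sqrt(1575 * 0.32 * 0.68))
  expect_identical(inject_failures(s, p, seed = 3), f)
})

test_that("rendered phantom VRI tracks the haze parameter monotonically", {
  g <- quick_geometry()
  haze <- c(0.01, 0.02, 0.05, 0.1, 0.15, 0.2)
  measured <- vapply(haze, function(v) {
    o <- phantom_optics(vitreous_mean = v, base_noise_sd = 0.02,
                        background_mean = 0.01)
    analyse_bscan(make_phantom(g, o, in_focus(), seed = 77))$vri
  }, numeric(1))
  expect_false(any(is.na(measured)))
  expect_true(all(diff(measured) >= 0))
})
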