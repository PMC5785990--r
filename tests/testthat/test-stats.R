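make_failed <- function(table, idx) {
  table$failed[idx] <- TRUE
  table$vri[idx] <- NA_real_
  table
}

test_that("exclusion rules drop sparse scans and sparse cells", {
  d <- protocol_arm(enumerate_protocol(4, 3, 7), "art")
  s <- generate_study(d, seed = 1)

  expect_equal(apply_exclusions(s), s,
               ignore_attr = TRUE)  # no failures anywhere

  # a scan with only 2 of 7 measured sections is dropped entirely
  hit <- with(s, subject == 1 & setting == "middle_art50_f0" &
                repetition == 1)
  s2 <- make_failed(s, which(hit)[1:5])
  e2 <- apply_exclusions(s2)
  expect_equal(sum(with(e2, subject == 1 & setting == "middle_art50_f0" &
                          repetition == 1)), 0L)
  # ...but its sibling repetitions survive
  expect_gt(sum(with(e2, subject == 1 & setting == "middle_art50_f0")), 0L)

  # a scan with exactly 3 measured sections is retained
  s3 <- make_failed(s, which(hit)[1:4])
  e3 <- apply_exclusions(s3)
  expect_equal(sum(with(e3, subject == 1 & setting == "middle_art50_f0" &
                          repetition == 1)), 3L)

  # losing 2 of 3 repetitions kills the whole subject x setting cell
  cell <- with(s, subject == 2 & setting == "middle_art6_f0")
  s4 <- make_failed(s, which(cell & s$repetition <= 2))
  e4 <- apply_exclusions(s4)
  expect_equal(sum(with(e4, subject == 2 & setting == "middle_art6_f0")), 0L)
  expect_true(any(attr(e4, "exclusion_log")$unit == "subject_setting_cell"))
})

test_that("exclusion is idempotent", {
  d <- protocol_arm(enumerate_protocol(5, 3, 7), "focus")
  s <- inject_failures(generate_study(d, seed = 3), seed = 4)
  once <- apply_exclusions(s)
  twice <- apply_exclusions(once)
  expect_equal(twice, once, ignore_attr = TRUE)
  expect_equal(nrow(attr(twice, "exclusion_log")), 0L)
})

test_that("failure rates follow the printed-percentage arithmetic", {
  slots <- enumerate_protocol(15, 3, 7)
  s <- generate_study(slots, seed = 1)
  fs0 <- failure_summary(slots, s)
  expect_true(all(fs0$failed == 0))
  expect_true(all(fs0$pct == 0))
  expect_equal(fs0$theoretical[fs0$arm == "art"], 1575L)
  expect_equal(fs0$theoretical[fs0$arm == "focus"], 1575L)
})

test_that("within-scan residuals are mean-centred per scan", {
  t <- tiny_table(c(0.04, 0.05, 0.06))
  r <- compute_level_residuals(t, "within_scan")
  expect_equal(r$residual, c(-0.01, 0, 0.01))
  expect_identical(r$squared_residual, r$residual^2)

  d <- protocol_arm(enumerate_protocol(6, 3, 7), "art")
  s <- generate_study(d, seed = 9)
  r2 <- compute_level_residuals(s, "within_scan")
  sums <- tapply(r2$residual,
                 paste(r2$subject, r2$setting, r2$repetition), sum)
  expect_lt(max(abs(sums)), 1e-12)
  # level-2 residuals centre per cell, level-3 per setting
  r3 <- compute_level_residuals(s, "intra_subject")
  expect_lt(max(abs(tapply(r3$residual,
                           paste(r3$subject, r3$setting), sum))), 1e-12)
  r4 <- compute_level_residuals(s, "inter_subject")
  expect_lt(max(abs(tapply(r4$residual, r4$setting, sum))), 1e-12)
})

test_that("constant tables give all-zero residuals at every level", {
  d <- protocol_arm(enumerate_protocol(3, 3, 7), "art")
  s <- generate_study(d, vc = variance_components(0, 0, 0), seed = 1)
  s$vri <- 0.05
  for (lv in c("within_scan", "intra_subject", "inter_subject"))
    expect_true(all(compute_level_residuals(s, lv)$residual == 0))
})

test_that("singleton groups contribute zero residuals and are flagged", {
  t <- tiny_table(0.05)
  r <- compute_level_residuals(t, "within_scan")
  expect_equal(r$residual, 0)
  expect_true(r$flagged)
})

test_that("mixed-model estimates equal cell means on balanced data", {
  d <- protocol_arm(enumerate_protocol(8, 3, 7), "art")
  s <- generate_study(d, seed = 21)
  fit <- fit_mean_model(s, "art")
  cell_means <- tapply(s$vri, factor(s$art, sort(unique(s$art))), mean)
  expect_equal(fit$estimates$estimate, unname(c(cell_means)),
               tolerance = 1e-6)
  expect_true(all(fit$varcorr >= 0))
  expect_equal(nrow(fit$estimates), 5L)
})

test_that("zero-variance data recover setting means with zero variances", {
  d <- protocol_arm(enumerate_protocol(4, 2, 3), "art")
  s <- generate_study(d, vc = variance_components(0, 0, 0), seed = 1)
  fit <- fit_mean_model(s, "art")
  mu <- reference_setting_means()
  expect_equal(fit$estimates$estimate,
               unname(mu[paste0("middle_art", fit$estimates$level, "_f0")]),
               tolerance = 1e-8)
  expect_lt(max(fit$varcorr), 1e-10)
  expect_lt(fit$p_overall, 0.001)
})

test_that("the mean model works for any response column", {
  d <- protocol_arm(enumerate_protocol(6, 3, 7), "focus")
  s <- generate_study(d, seed = 31)
  fit <- fit_mean_model(s, "focus", response = "vitreous_mean")
  expect_equal(fit$estimates$estimate,
               0.85 * fit_mean_model(s, "focus")$estimates$estimate,
               tolerance = 1e-6)
})

test_that("Gamma-GLM variability equals the per-group RMS oracle", {
  d <- protocol_arm(enumerate_protocol(6, 3, 7), "art")
  s <- generate_study(d, vc = variance_components(0.012, 0.007, 0.010),
                      seed = 13)
  for (lv in c("within_scan", "intra_subject", "inter_subject")) {
    r <- compute_level_residuals(s, lv)
    vf <- fit_variability(r, "art")
    oracle <- rms_by_group(r, "art")
    expect_equal(vf$estimates$variability, unname(oracle),
                 tolerance = 1e-8)
  }
})

test_that("constant squared residuals give variability sqrt(c)", {
  t <- tiny_table(rep(c(0.04, 0.06), 6), repetition = rep(1:2, each = 6))
  t$section <- rep(1:6, 2)
  r <- compute_level_residuals(t, "within_scan")
  expect_equal(r$squared_residual, rep(1e-4, 12))
  vf <- fit_variability(r, "art")
  expect_equal(vf$estimates$variability, 0.01, tolerance = 1e-10)
})

test_that("zero squared residuals are dropped with an accounting", {
  t <- tiny_table(rep(c(0.04, 0.06), 6), repetition = rep(1:2, each = 6))
  t$section <- rep(1:6, 2)
  r <- compute_level_residuals(t, "within_scan")
  r$squared_residual[1] <- 0
  vf <- fit_variability(r, "art")
  expect_equal(vf$n_zero_dropped, 1L)
})

test_that("two-level contrasts need no multiplicity adjustment", {
  d <- protocol_arm(enumerate_protocol(8, 3, 7), "position")
  s <- generate_study(d, seed = 17)
  fit <- fit_mean_model(s, "position")
  pw <- pairwise_compare(fit)
  expect_equal(nrow(pw), 1L)
  emm <- emmeans::emmeans(fit$fit, "fac", data = fit$data)
  unadj <- summary(emmeans::contrast(emm, "pairwise"), adjust = "none")
  expect_equal(pw$p_adj, unadj$p.value, tolerance = 1e-12)
})

test_that("a level shifted by five generating sds shows in its contrasts", {
  d <- protocol_arm(enumerate_protocol(10, 3, 7), "art")
  mu <- reference_setting_means()
  mu[] <- 0.045
  mu["middle_art100_f0"] <- 0.045 + 5 * 0.012
  s <- generate_study(d, mu, variance_components(0.012, 0.007, 0.010),
                      seed = 23)
  pw <- pairwise_compare(fit_mean_model(s, "art"))
  has100 <- grepl("fac100", pw$contrast)
  expect_true(all(pw$p_adj[has100] < 0.05))
  expect_true(all(pw$p_adj[!has100] > 0.05))
})

test_that("null pairwise comparisons rarely flag differences", {
  mu <- reference_setting_means()
  mu[] <- 0.045
  d <- protocol_arm(enumerate_protocol(8, 3, 7), "art")
  clean <- vapply(1:20, function(i) {
    s <- generate_study(d, mu, variance_components(0.012, 0.007, 0.010),
                        seed = 1000 + i)
    all(pairwise_compare(fit_mean_model(s, "art"))$p_adj > 0.05)
  }, logical(1))
  expect_gte(sum(clean), 17)
})

test_that("variance-component recovery is close on one large study", {
  d <- enumerate_protocol(15, 3, 7)
  s <- generate_study(d, vc = variance_components(0.012, 0.007, 0.010),
                      seed = 99)
  rv <- recover_variance_components(s)
  expect_equal(unname(rv["sigma_section"]), 0.010, tolerance = 0.1)
  expect_equal(unname(rv["sigma_scan"]), 0.007, tolerance = 0.25)
  expect_equal(unname(rv["sigma_subject"]), 0.012, tolerance = 0.35)
})

test_that("box-plot summaries follow the 1.5 IQR whisker rule", {
  b <- boxplot_stats(1:100)
  expect_equal(b$median, 50.5)
  expect_equal(b$q1, 25.75)
  expect_equal(b$q3, 75.25)
  expect_length(b$outliers, 0)
  expect_equal(b$whisker_low, 1)
  expect_equal(b$whisker_high, 100)

  const <- boxplot_stats(rep(3, 10))
  expect_equal(const$iqr, 0)
  expect_length(const$outliers, 0)

  out <- boxplot_stats(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)
  expect_error(boxplot_stats(numeric(0)), "no finite values")
})
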