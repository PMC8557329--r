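fiber_records <- function(coverage, intensity = rep(1000, length(coverage))) {
  n <- length(coverage)
  data.frame(fiber_id = seq_len(n), cx = rep(0, n), cy = rep(0, n),
             area_px = rep(100, n),
             mean_intensity_au = intensity, coverage_pct = coverage,
             positive = classify_positive(coverage),
             bin = assign_bin(coverage))
}

test_that("summarize_section computes the whole-section metrics", {
  # all fibers at full coverage -> 100% positive, all mass in B4
  s <- summarize_section(fiber_records(rep(100, 10)))
  expect_equal(s$pct_positive, 100)
  expect_equal(unname(s$bin_fractions), c(0, 0, 0, 1))

  # unweighted mean of per-fiber intensities
  s2 <- summarize_section(fiber_records(c(80, 90), intensity = c(10, 30)))
  expect_equal(s2$mean_intensity, 20)

  # pct_positive is exactly the positive-record fraction and 100*(1 - B1)
  cov <- c(0, 10, 24.9, 25, 30, 60, 75, 100)
  s3 <- summarize_section(fiber_records(cov))
  expect_equal(s3$pct_positive, 100 * mean(classify_positive(cov)))
  expect_equal(s3$pct_positive, 100 * (1 - s3$bin_fractions[["B1"]]))
  expect_equal(sum(s3$bin_fractions), 1, tolerance = 1e-9)

  # per-bin mean intensity bounded by member extremes
  s4 <- summarize_section(fiber_records(c(80, 85, 90), c(5, 10, 30)))
  expect_gte(s4$bin_mean_intensity[["B4"]], 5)
  expect_lte(s4$bin_mean_intensity[["B4"]], 30)

  expect_error(summarize_section(fiber_records(numeric(0))), "no fiber")
})

test_that("a DMD-preset simulation yields ~48% positive fibers", {
  gt <- sample_fibers(phenotype_preset("DMD"), 5000, seed = 19)
  rec <- fiber_records(100 * gt$true_coverage, gt$true_intensity)
  s <- summarize_section(rec)
  expect_lt(abs(s$pct_positive - 48), 2)
})

test_that("summarize_subject reproduces the two-replicate mean +/- SD rule", {
  mk <- function(pct, int = 1000) {
    structure(list(n_fibers = 10, mean_intensity = int, pct_positive = pct,
                   bin_fractions = c(B1 = 0, B2 = 0, B3 = 0, B4 = 1),
                   bin_mean_intensity = rep(int, 4)),
              class = "section_summary")
  }
  # replicates {99, 100} -> 99.5 +/- 0.7 (printed rounding)
  s <- summarize_subject(mk(99), mk(100), "p3", "mildBMD")
  expect_equal(unname(s$pct_positive["mean"]), 99.5)
  expect_equal(round(unname(s$pct_positive["sd"]), 1), 0.7)
  # closed form SD = |a - b| / sqrt(2)
  s2 <- summarize_subject(mk(98), mk(102), "x", "DMD")
  expect_equal(unname(s2$pct_positive["sd"]), 4 / sqrt(2))
  # identical replicates -> SD 0; order invariance of the mean
  s3 <- summarize_subject(mk(70), mk(70), "y", "DMD")
  expect_equal(unname(s3$pct_positive["sd"]), 0)
  s4 <- summarize_subject(mk(100, 30), mk(98, 10), "z", "CTRL")
  s5 <- summarize_subject(mk(98, 10), mk(100, 30), "z", "CTRL")
  expect_equal(s4$mean_intensity, s5$mean_intensity)
  expect_error(summarize_subject(mk(99)), "exactly 2 replicate")
})

test_that("ecdf_points is a right-continuous CDF ending at 1", {
  e1 <- ecdf_points(5)
  expect_equal(e1$value, 5)
  expect_equal(e1$frac, 1)
  e2 <- ecdf_points(c(3, 1, 2, 4))
  expect_equal(e2$value, 1:4)
  expect_equal(e2$frac[e2$value == 2], 0.5)
  expect_true(all(diff(e2$frac) >= 0))
  expect_equal(max(e2$frac), 1)
  expect_error(ecdf_points(numeric(0)), "empty")
})

test_that("sampled intensity ECDF converges to the preset lognormal law", {
  p <- phenotype_preset("DMD")
  s <- sample_fibers(p, 10000, seed = 23)
  e <- ecdf_points(s$true_intensity)
  s2 <- log(1 + p$intensity_cv^2)
  keep <- e$value < 65535          # censoring at the 16-bit ceiling
  theor <- plnorm(e$value[keep], log(p$intensity_mean) - s2 / 2, sqrt(s2))
  expect_lte(max(abs(e$frac[keep] - theor)), 0.02)
})
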