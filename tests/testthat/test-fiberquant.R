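test_that("measure_intensity is the plain ring-pixel mean", {
  out <- disk_section(radius = 20, ring_width = 3)
  labels <- segment_fibers(out$image$LAMA2)
  rings <- extract_ring(labels, ring_width = 3)
  # uniform dystrophin field at v -> exactly v
  uniform <- matrix(1234L, 64, 64)
  expect_identical(unname(measure_intensity(uniform, rings)), 1234)
  # noiseless full-coverage render at I with the band as the ring -> I
  expect_equal(unname(measure_intensity(out$image$DYS, rings)), 40000,
               tolerance = 1e-8)
})

test_that("half-coverage noiseless fiber measures half the arc intensity", {
  out <- disk_section(radius = 20, ring_width = 3, coverage = 0.5,
                      intensity = 40000, background = 0)
  labels <- segment_fibers(out$image$LAMA2)
  rings <- extract_ring(labels, ring_width = 3)
  m <- unname(measure_intensity(out$image$DYS, rings))
  expect_lt(abs(m / 20000 - 1), 0.05)
})

test_that("measure_coverage recovers noiseless arc fractions", {
  for (cv in c(0.25, 0.5, 0.75)) {
    out <- disk_section(radius = 20, ring_width = 3, coverage = cv,
                        phase = 0.7)
    labels <- segment_fibers(out$image$LAMA2)
    rings <- extract_ring(labels, ring_width = 3)
    got <- unname(measure_coverage(out$image$DYS, rings, labels = labels))
    expect_lt(abs(got - 100 * cv), 2)
  }
})

test_that("degenerate thresholds behave as specified", {
  out <- disk_section(radius = 20, coverage = 0.5, background = 0)
  labels <- segment_fibers(out$image$LAMA2)
  rings <- extract_ring(labels, ring_width = 3)
  # null signal, positive threshold -> 0%
  zeros <- matrix(0L, 64, 64)
  expect_equal(as.numeric(measure_coverage(zeros, rings,
                                           positivity_threshold = 10)), 0)
  # threshold 0 -> 100% for any fiber
  expect_equal(as.numeric(measure_coverage(out$image$DYS, rings,
                                           positivity_threshold = 0)), 100)
  # threshold beyond the 16-bit range is a config error
  expect_error(measure_coverage(out$image$DYS, rings,
                                positivity_threshold = 70000),
               "16-bit")
})

test_that("positivity and bin assignment agree over an exhaustive sweep", {
  cov <- seq(0, 100, by = 0.1)
  pos <- classify_positive(cov)
  bins <- assign_bin(cov)
  # boundary conventions
  expect_false(classify_positive(24.9))
  expect_true(classify_positive(25))
  expect_true(classify_positive(100))
  expect_identical(as.character(assign_bin(c(0, 25, 52, 75, 100))),
                   c("B1", "B2", "B3", "B4", "B4"))
  # every coverage in exactly one bin; positive <=> not B1
  expect_false(anyNA(bins))
  expect_identical(pos, bins != "B1")
  # out-of-range inputs rejected
  expect_error(classify_positive(-1), "0, 100")
  expect_error(assign_bin(101), "0, 100")
})

test_that("coverage recovery meets accuracy floors on a default-noise section", {
  cfg <- render_config(image_size = c(768, 768), seed = 17)
  sim <- simulate_section("DMD", 500, cfg, seed = 17)
  q <- run_quantify(sim$image)
  m <- match_ground_truth(sim$truth, q$records)
  err <- m$coverage_pct - 100 * m$true_coverage
  expect_gte(nrow(m), 450)
  expect_lte(mean(abs(err)), 5)
  expect_gte(cor(m$coverage_pct, 100 * m$true_coverage), 0.95)
})

test_that("intensity recovery slope is ~1 on noiseless full-coverage fibers", {
  cfg <- render_config(image_size = c(384, 384), noise_sd = 0, blur_sigma = 0)
  set.seed(5)
  out <- full_coverage_section(80, runif(80, 5000, 60000), cfg, seed = 13)
  q <- run_quantify(out$image)
  m <- match_ground_truth(out$truth, q$records)
  slope <- coef(lm(mean_intensity_au ~ true_intensity, data = m))[2]
  expect_gte(slope, 0.9)
  expect_lte(slope, 1.1)
})
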