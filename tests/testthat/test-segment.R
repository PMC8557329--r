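test_that("segmentation recovers every interior fiber of a clean section", {
  cfg <- render_config(image_size = c(512, 512), noise_sd = 0, blur_sigma = 0)
  out <- full_coverage_section(100, 30000, cfg, seed = 21)
  n_true <- nrow(out$truth)
  labels <- segment_fibers(out$image$LAMA2)
  expect_identical(labels$n_fibers, n_true)
  # each ground-truth centroid falls in exactly one label, all distinct
  hits <- vapply(seq_len(n_true), function(i) {
    labels$labels[round(out$truth$cy[i]), round(out$truth$cx[i])]
  }, integer(1))
  expect_true(all(hits > 0))
  expect_identical(length(unique(hits)), n_true)
})

test_that("degenerate laminin inputs are rejected", {
  expect_error(segment_fibers(matrix(0L, 64, 64)), "no fibers segmented")
  expect_error(segment_fibers(matrix(500L, 64, 64)), "no fibers segmented")
})

test_that("fibers touching the frame border are excluded", {
  # a fiber cut by the frame: three laminin walls, open to the left border
  lam <- matrix(800L, 64, 64)
  lam[20:40, 28:30] <- 30000L
  lam[20:22, 1:30] <- 30000L
  lam[38:40, 1:30] <- 30000L
  labels <- segment_fibers(lam, min_area = 50)
  expect_identical(labels$n_fibers, 0L)
  expect_gte(labels$meta$n_excluded_border, 1L)

  # the same ring shifted inside the frame is kept
  lam2 <- matrix(800L, 64, 64)
  lam2[20:40, 11:13] <- 30000L
  lam2[20:40, 38:40] <- 30000L
  lam2[20:22, 11:40] <- 30000L
  lam2[38:40, 11:40] <- 30000L
  expect_identical(segment_fibers(lam2, min_area = 50)$n_fibers, 1L)
})

test_that("ring extraction matches the analytic annulus of a disk", {
  out <- disk_section(radius = 20, ring_width = 3, size = 64)
  labels <- segment_fibers(out$image$LAMA2)
  rings <- extract_ring(labels, ring_width = 3)
  expected <- pi * (20^2 - 17^2)
  expect_lt(abs(nrow(rings$pixels) / expected - 1), 0.10)
  expect_false(any(rings$whole_fiber))
})

test_that("a ring wider than the fiber radius saturates and is flagged", {
  out <- disk_section(radius = 8, ring_width = 3, size = 32)
  labels <- segment_fibers(out$image$LAMA2, min_area = 20)
  rings <- extract_ring(labels, ring_width = 20)
  expect_true(all(rings$whole_fiber))
  expect_identical(nrow(rings$pixels), sum(labels$sizes))
})

test_that("arc parameterization covers all K segments for a large square fiber", {
  lam <- matrix(800L, 200, 200)
  sq <- matrix(0L, 200, 200)
  sq[20:180, 20:180] <- 1L
  inner <- dysquant:::.peel_labels(sq, 3L, FALSE)
  band <- sq == 1L & inner == 0L
  lam[band] <- 30000L
  labels <- segment_fibers(lam)
  rings <- extract_ring(labels, ring_width = 3, K = 360)
  expect_identical(labels$n_fibers, 1L)
  expect_identical(sort(unique(rings$pixels$arc)), 1:360)
})

test_that("rings of distinct fibers are disjoint pixel sets", {
  cfg <- render_config(image_size = c(384, 384), noise_sd = 0, blur_sigma = 0)
  out <- full_coverage_section(60, 30000, cfg, seed = 8)
  labels <- segment_fibers(out$image$LAMA2)
  rings <- extract_ring(labels, ring_width = 3)
  key <- paste(rings$pixels$r, rings$pixels$c)
  expect_identical(anyDuplicated(key), 0L)
})

test_that("segmentation recall holds on noiseless and default-noise renders", {
  # fiber areas are kept well above min_area, where the debris filter is
  # inert and recall against ground truth is meaningful
  for (case in list(list(noise = 0, blur = 0, floor = 0.98),
                    list(noise = 2519, blur = 0.8, floor = 0.90))) {
    cfg <- render_config(image_size = c(512, 512), noise_sd = case$noise,
                         blur_sigma = case$blur, seed = 31)
    sim <- simulate_section("CTRL", 200, cfg, seed = 31)
    labels <- segment_fibers(sim$image$LAMA2)
    hits <- vapply(seq_len(nrow(sim$truth)), function(i) {
      labels$labels[round(sim$truth$cy[i]), round(sim$truth$cx[i])]
    }, integer(1))
    recall <- length(unique(hits[hits > 0])) / nrow(sim$truth)
    precision <- length(unique(hits[hits > 0])) / labels$n_fibers
    expect_gte(recall, case$floor)
    expect_gte(precision, case$floor)
  }
})
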