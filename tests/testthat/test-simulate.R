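test_that("generate_geometry satisfies its contract on edge and bulk cases", {
  # single fiber fully inside the frame
  one <- generate_geometry(1, c(64, 64), gap = 2, seed = 0)
  expect_length(one, 1)
  poly <- one[[1]]$polygon
  expect_true(all(poly[, 1] >= 1 & poly[, 1] <= 64))
  expect_true(all(poly[, 2] >= 1 & poly[, 2] <= 64))

  # determinism
  a <- generate_geometry(100, c(1024, 1024), gap = 2, seed = 7)
  b <- generate_geometry(100, c(1024, 1024), gap = 2, seed = 7)
  expect_identical(a, b)
  expect_gte(length(a), 90)

  # all-pairs polygon intersection area is zero (brute-force oracle)
  polys <- lapply(a, function(f) open_polygon(f$polygon))
  pairs <- utils::combn(length(polys), 2)
  areas <- vapply(seq_len(ncol(pairs)), function(k) {
    convex_intersection_area(polys[[pairs[1, k]]], polys[[pairs[2, k]]])
  }, numeric(1))
  expect_true(all(areas == 0))

  # sizing error names the constraint
  expect_error(generate_geometry(1000, c(64, 64), gap = 2, seed = 1),
               "too small")
})

test_that("fibers of a mosaic stay separated by the requested gap", {
  geo <- generate_geometry(80, c(512, 512), gap = 4, seed = 5)
  H <- 512L
  lab <- matrix(0L, H, H)
  for (f in geo) {
    px <- dysquant:::rasterize_polygon(f$polygon, H, H)
    expect_true(all(lab[px] == 0L))      # rasterized masks disjoint
    lab[px] <- f$fiber_id
  }
  # no two distinct labels within Chebyshev distance floor(gap/2)
  d <- 2L
  conflicts <- 0L
  for (dr in -d:d) for (dc in -d:d) {
    if (dr == 0 && dc == 0) next
    a <- lab[pmax(1, pmin(H, seq_len(H) + dr)), pmax(1, pmin(H, seq_len(H) + dc))]
    conflicts <- conflicts + sum(lab > 0 & a > 0 & lab != a)
  }
  expect_identical(conflicts, 0L)
})

test_that("sample_fibers reproduces preset coverage-bin compositions", {
  # all control fibers sit in the 75-100% coverage class
  ctrl <- sample_fibers(phenotype_preset("CTRL"), 500, seed = 2)
  expect_true(all(ctrl$true_coverage >= 0.75))

  # DMD composition converges to 52/30/12/6 within +/- 0.02
  dmd <- sample_fibers(phenotype_preset("DMD"), 10000, seed = 1)
  emp <- as.numeric(table(cut(dmd$true_coverage, c(0, 0.25, 0.5, 0.75, 1),
                              include.lowest = TRUE, right = FALSE))) / 10000
  expect_true(all(abs(emp - c(0.52, 0.30, 0.12, 0.06)) <= 0.02))

  # zero-CV presets are degenerate at the mean
  flat <- sample_fibers(phenotype_preset("DMD", intensity_cv = 0), 50, seed = 1)
  expect_true(all(flat$true_intensity == 11947))

  # determinism and range invariants across all presets
  for (nm in c("CTRL", "mildBMD", "severeBMD-like-mild",
               "severeBMD-like-DMD", "IMD", "DMD")) {
    s1 <- sample_fibers(phenotype_preset(nm), 200, seed = 9)
    s2 <- sample_fibers(phenotype_preset(nm), 200, seed = 9)
    expect_identical(s1, s2)
    expect_true(all(s1$true_coverage >= 0 & s1$true_coverage <= 1))
    expect_true(all(s1$true_intensity >= 0 & s1$true_intensity <= 65535))
  }
})

test_that("preset bin fractions are validated", {
  expect_error(phenotype_preset("DMD", bin_fractions = c(0.5, 0.3, 0.1, 0.05)),
               "sum to 1")
  expect_error(phenotype_preset("nope"), "unknown phenotype preset")
})

test_that("render_section draws exact noiseless geometry and is deterministic", {
  out <- disk_section(radius = 18, coverage = 1, intensity = 40000)
  img <- out$image
  expect_true(is.integer(img$DYS) && is.integer(img$LAMA2))
  expect_true(min(img$DYS, img$LAMA2) >= 0 && max(img$DYS, img$LAMA2) <= 65535)
  # every laminin-band (boundary) pixel carries the dystrophin intensity
  band <- img$LAMA2 == 30000
  expect_gt(sum(band), 0)
  expect_true(all(img$DYS[band] == 40000))
  expect_true(all(img$DYS[!band] == 800))
  expect_equal(nrow(out$truth), 1)

  cfg <- render_config(image_size = c(256, 256), seed = 3)
  geo <- generate_geometry(30, c(256, 256), gap = 3, seed = 4)
  for (i in seq_along(geo)) {
    geo[[i]]$true_coverage <- 0.6
    geo[[i]]$true_intensity <- 20000
    geo[[i]]$arc_phase <- 1
  }
  r1 <- render_section(geo, cfg)
  r2 <- render_section(geo, cfg)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$truth, r2$truth)
  expect_false(anyDuplicated(r1$truth$fiber_id) > 0)
})

test_that("half-coverage fiber lights up half its ring pixels", {
  out <- disk_section(radius = 20, coverage = 0.5, intensity = 40000,
                      phase = 0.3)
  img <- out$image
  band <- img$LAMA2 == 30000
  frac <- mean(img$DYS[band] > 800)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("rendered ring mean intensity is monotone in true intensity", {
  theta <- seq(0, 2 * pi, length.out = 100)[-1]
  poly <- cbind(r = 33 + 20 * sin(theta), c = 33 + 20 * cos(theta))
  cfg <- render_config(image_size = c(64, 64), noise_sd = 500,
                       blur_sigma = 0.8, seed = 11)
  ref <- disk_section(radius = 20, coverage = 1)$image
  band <- ref$LAMA2 == 30000
  means <- vapply(c(5000, 15000, 30000, 45000, 60000), function(I) {
    fib <- list(list(fiber_id = 1L, polygon = rbind(poly, poly[1, ]),
                     true_coverage = 1, true_intensity = I, arc_phase = 0))
    mean(render_section(fib, cfg)$image$DYS[band])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("simulate_section wires geometry, ground truth and phases together", {
  sim <- simulate_section("DMD", 60, render_config(image_size = 256), seed = 9)
  expect_s3_class(sim$image, "section_image")
  expect_equal(nrow(sim$truth), length(sim$fibers))
  expect_true(all(sim$truth$area_px > 50))
  sim2 <- simulate_section("DMD", 60, render_config(image_size = 256), seed = 9)
  expect_identical(sim$image, sim2$image)
})
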