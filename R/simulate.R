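# Synthetic two-channel muscle-section simulator.
#
# A section is a mosaic of convex-ish fiber polygons (Lloyd-relaxed Voronoi
# cells eroded to leave interstitial space), each carrying a ground-truth
# sarcolemmal dystrophin coverage fraction and intensity. Rendering draws
# the laminin ring along every fiber boundary and the dystrophin signal on a
# contiguous boundary arc, then applies optical blur, sensor noise and
# 16-bit quantization.

#' Render configuration for the section simulator
#'
#' @param image_size integer (H, W) in pixels; a scalar is used for both.
#' @param ring_width sarcolemmal band width in pixels (>= 1).
#' @param laminin_intensity AU of the laminin ring.
#' @param background_level AU of unstained tissue/interstitium.
#' @param noise_sd additive Gaussian sensor noise, AU. The default (2519 AU)
#'   puts the control preset (~50,387 AU) at SNR ~ 20.
#' @param blur_sigma Gaussian optical blur, pixels.
#' @param pixel_size_um physical pixel size, micrometres.
#' @param seed integer seed for the render's noise stream.
#' @return list of class `render_config`.
#' @export
render_config <- function(image_size = c(512L, 512L), ring_width = 3L,
                          laminin_intensity = 30000, background_level = 800,
                          noise_sd = 2519, blur_sigma = 0.8,
                          pixel_size_um = 0.5, seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  cfg <- list(image_size = as.integer(image_size), ring_width = as.integer(ring_width),
              laminin_intensity = laminin_intensity,
              background_level = background_level, noise_sd = noise_sd,
              blur_sigma = blur_sigma, pixel_size_um = pixel_size_um,
              seed = as.integer(seed))
  if (cfg$ring_width < 1L) stopf("ring_width must be >= 1")
  for (f in c("laminin_intensity", "background_level", "noise_sd")) {
    if (cfg[[f]] < 0 || cfg[[f]] > MAX_AU) {
      stopf("%s must lie in [0, %d] AU", f, MAX_AU)
    }
  }
  structure(cfg, class = "render_config")
}

#' Generate a non-overlapping fiber polygon mosaic
#'
#' Poisson-sampled seed points are Lloyd-relaxed for a few iterations, the
#' resulting Voronoi cells are eroded by `ceiling(gap/2)` pixels (plus a
#' fixed 4-pixel frame margin) and each surviving cell is returned as the
#' convex hull of its pixels. The erosion creates the interstitial space in
#' which the laminin network of a real transverse section lives.
#'
#' @param n_fibers requested number of fibers (>= 1).
#' @param image_size (H, W) in pixels.
#' @param gap minimum interstitial separation between fibers, pixels (>= 1).
#' @param seed integer seed; the mosaic is deterministic given the seed.
#' @param lloyd_iters Lloyd relaxation sweeps (default 3).
#' @return list of fiber polygons; each element has `fiber_id` and `polygon`
#'   (closed matrix with columns r, c in pixel-centre coordinates).
#' @export
generate_geometry <- function(n_fibers, image_size, gap = 2L, seed = 1L,
                              lloyd_iters = 3L) {
  stopifnot(n_fibers >= 1, gap >= 1)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  margin <- 4L
  usable <- (H - 2L * margin) * (W - 2L * margin)
  if (usable / n_fibers < 100) {
    stopf(paste("image too small for requested fiber count:",
                "%d x %d px supports at most %d fibers at a mean area",
                ">= 100 px (requested %d)"),
          H, W, floor(usable / 100), n_fibers)
  }
  rows <- as.vector(row(matrix(0L, H, W)))
  cols <- as.vector(col(matrix(0L, H, W)))
  with_seed(seed, {
    sr <- stats::runif(n_fibers, margin + 1, H - margin)
    sc <- stats::runif(n_fibers, margin + 1, W - margin)
    for (i in seq_len(lloyd_iters)) {
      lab <- .nearest_seed_label(H, W, sr, sc)
      g <- factor(as.vector(lab), levels = seq_len(n_fibers))
      cnt <- as.vector(rowsum(rep(1, H * W), g))
      nr <- as.vector(rowsum(rows, g)) / cnt
      nc <- as.vector(rowsum(cols, g)) / cnt
      ok <- is.finite(nr) & is.finite(nc)
      sr[ok] <- nr[ok]
      sc[ok] <- nc[ok]
    }
    lab <- .nearest_seed_label(H, W, sr, sc)
  })
  # frame margin, then erosion to carve the interstitial gap
  lab[c(seq_len(margin), H - margin + seq_len(margin)), ] <- 0L
  lab[, c(seq_len(margin), W - margin + seq_len(margin))] <- 0L
  lab <- .peel_labels(lab, ceiling(gap / 2), TRUE)
  keep <- which(tabulate(lab, n_fibers) >= 50)
  if (length(keep) < 0.9 * n_fibers) {
    stopf(paste("image too small for requested fiber count: only %d of %d",
                "cells survive a gap of %d px at mean area >= 100 px"),
          length(keep), n_fibers, gap)
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  pr <- split((idx - 1L) %% H + 1L, ids)
  pc <- split((idx - 1L) %/% H + 1L, ids)
  fibers <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- as.character(keep[i])
    hull <- grDevices::chull(pc[[k]], pr[[k]])
    poly <- cbind(r = pr[[k]][hull], c = pc[[k]][hull])
    fibers[[i]] <- list(fiber_id = i, polygon = rbind(poly, poly[1, , drop = FALSE]))
  }
  fibers
}

#' Sample per-fiber ground-truth coverage and intensity from a preset
#'
#' Coverage is drawn hierarchically: a coverage bin from the preset's
#' `bin_fractions`, then uniform within the bin's coverage range. Intensity
#' is lognormal with the preset's arithmetic mean and CV, censored to the
#' 16-bit range.
#'
#' @param preset a [phenotype_preset()].
#' @param n_fibers number of fibers.
#' @param seed integer seed.
#' @return data.frame with columns `true_coverage` (fraction in \[0,1\]) and
#'   `true_intensity` (AU).
#' @export
sample_fibers <- function(preset, n_fibers, seed = 1L) {
  validate_preset(preset)
  stopifnot(n_fibers >= 1)
  lo <- c(0, 0.25, 0.50, 0.75)
  hi <- c(0.25, 0.50, 0.75, 1)
  with_seed(seed, {
    bin <- sample.int(4L, n_fibers, replace = TRUE, prob = preset$bin_fractions)
    cov <- stats::runif(n_fibers, lo[bin], hi[bin])
    if (preset$intensity_cv == 0) {
      int <- rep(preset$intensity_mean, n_fibers)
    } else {
      s2 <- log(1 + preset$intensity_cv^2)
      int <- stats::rlnorm(n_fibers,
                           meanlog = log(preset$intensity_mean) - s2 / 2,
                           sdlog = sqrt(s2))
    }
  })
  data.frame(true_coverage = cov, true_intensity = clamp16(int))
}

#' Render a two-channel section image from fiber specifications
#'
#' The laminin channel carries a ring of `ring_width` pixels along every
#' fiber boundary; the dystrophin channel carries `true_intensity` on the
#' contiguous boundary arc of angular length `2*pi*true_coverage` starting
#' at `arc_phase`, and `background_level` elsewhere. Both channels are
#' blurred, noised, clipped to \[0, 65535\] and quantized.
#'
#' @param fibers list of fiber specs: each element needs `fiber_id`,
#'   `polygon` (closed (r,c) matrix), `true_coverage`, `true_intensity` and
#'   `arc_phase` (radians).
#' @param config a [render_config()].
#' @return list with `image` (a `section_image`) and `truth` (the
#'   ground-truth data.frame: fiber_id, true_coverage, true_intensity,
#'   cx, cy, area_px).
#' @export
render_section <- function(fibers, config) {
  stopifnot(inherits(config, "render_config"))
  H <- config$image_size[1]; W <- config$image_size[2]
  dys <- matrix(config$background_level, H, W)
  lam <- matrix(config$background_level, H, W)
  truth <- vector("list", length(fibers))
  for (fi in seq_along(fibers)) {
    fb <- fibers[[fi]]
    poly <- fb$polygon
    if (min(poly[, 1]) < 0.5 || max(poly[, 1]) > H + 0.5 ||
        min(poly[, 2]) < 0.5 || max(poly[, 2]) > W + 0.5) {
      stopf("fiber %d extends outside the %d x %d frame", fb$fiber_id, H, W)
    }
    px <- rasterize_polygon(poly, H, W)
    # peel on the fiber's padded bounding box only (performance)
    r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
    lpx <- cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)
    mask <- matrix(0L, max(lpx[, 1]) + 1L, max(lpx[, 2]) + 1L)
    mask[lpx] <- 1L
    inner <- .peel_labels(mask, config$ring_width, FALSE)
    band <- px[inner[lpx] == 0L, , drop = FALSE]
    lam[band] <- config$laminin_intensity
    cr <- mean(px[, 1]); cc <- mean(px[, 2])
    if (fb$true_coverage > 0) {
      theta <- pixel_angle(band[, 1], band[, 2], cr, cc)
      rel <- (theta - fb$arc_phase) %% (2 * pi)
      on_arc <- rel < 2 * pi * fb$true_coverage
      dys[band[on_arc, , drop = FALSE]] <- fb$true_intensity
    }
    truth[[fi]] <- data.frame(
      fiber_id = fb$fiber_id, true_coverage = fb$true_coverage,
      true_intensity = fb$true_intensity, cx = cc, cy = cr,
      area_px = nrow(px))
  }
  truth <- do.call(rbind, truth)
  stopifnot(!anyDuplicated(truth$fiber_id))
  finish <- function(ch) {
    ch <- blur_gaussian(ch, config$blur_sigma)
    if (config$noise_sd > 0) {
      ch <- ch + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
    }
    matrix(as.integer(round(clamp16(ch))), H, W)
  }
  img <- with_seed(config$seed, {
    list(DYS = finish(dys), LAMA2 = finish(lam))
  })
  list(image = section_image(img$DYS, img$LAMA2, config$pixel_size_um),
       truth = truth)
}

#' Construct a two-channel section image container
#'
#' @param dys,lam integer matrices (16-bit AU) of the dystrophin and
#'   laminin-alpha-2 channels; identical dimensions.
#' @param pixel_size_um physical pixel size.
#' @return object of class `section_image`: a named list of channel
#'   matrices `DYS` and `LAMA2` plus `pixel_size_um`.
#' @export
section_image <- function(dys, lam, pixel_size_um = 0.5) {
  stopifnot(is.matrix(dys), is.matrix(lam), all(dim(dys) == dim(lam)))
  if (min(dys, lam) < 0 || max(dys, lam) > MAX_AU) {
    stopf("pixel values must lie in [0, %d]", MAX_AU)
  }
  structure(list(DYS = dys, LAMA2 = lam, pixel_size_um = pixel_size_um),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, channels DYS/LAMA2, %.3g um/px\n",
              nrow(x$DYS), ncol(x$DYS), x$pixel_size_um))
  invisible(x)
}

#' Simulate a complete synthetic section for a phenotype
#'
#' Convenience wrapper chaining [generate_geometry()], [sample_fibers()] and
#' [render_section()]; the single `seed` drives the geometry, the fiber
#' ground truth, the random arc phases and the render noise.
#'
#' @param preset a [phenotype_preset()] or preset name.
#' @param n_fibers number of fibers requested.
#' @param config a [render_config()]; its `seed` is overridden by `seed`.
#' @param gap interstitial gap in pixels (default 3, ~1.5 um of endomysium
#'   at the default pixel size).
#' @param seed integer seed.
#' @return list with `image`, `truth`, and `fibers` (the specs).
#' @export
simulate_section <- function(preset, n_fibers, config = render_config(),
                             gap = 3L, seed = 1L) {
  if (is.character(preset)) preset <- phenotype_preset(preset)
  config$seed <- as.integer(seed)
  fibers <- generate_geometry(n_fibers, config$image_size, gap = gap,
                              seed = seed)
  gt <- sample_fibers(preset, length(fibers), seed = seed + 1L)
  phases <- with_seed(seed + 2L, stats::runif(length(fibers), 0, 2 * pi))
  for (i in seq_along(fibers)) {
    fibers[[i]]$true_coverage <- gt$true_coverage[i]
    fibers[[i]]$true_intensity <- gt$true_intensity[i]
    fibers[[i]]$arc_phase <- phases[i]
  }
  out <- render_section(fibers, config)
  out$fibers <- fibers
  out
}
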