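# Per-fiber dystrophin metrics: sarcolemmal mean intensity, circumference
# coverage, positivity and coverage bin.

COVERAGE_BINS <- c("B1", "B2", "B3", "B4")

#' Mean dystrophin intensity over a fiber's sarcolemmal ring
#'
#' Arithmetic mean of raw dystrophin pixel values (AU) over the ring pixels;
#' no background subtraction is applied.
#'
#' @param dys dystrophin channel (matrix) or `section_image`.
#' @param rings a `sarcolemmal_rings` object.
#' @return named numeric vector of AU means, one per fiber.
#' @export
measure_intensity <- function(dys, rings) {
  if (inherits(dys, "section_image")) dys <- dys$DYS
  stopifnot(inherits(rings, "sarcolemmal_rings"))
  px <- rings$pixels
  if (nrow(px) == 0L) stopf("empty sarcolemmal ring")
  v <- dys[cbind(px$r, px$c)]
  out <- tapply(v, px$fiber_id, mean)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}

#' Automatic positivity threshold from interstitial background
#'
#' Mode of the interstitial (non-fiber) dystrophin pixels plus three times
#' their median absolute deviation (scaled, as in [stats::mad()]), plus a
#' half-AU quantization offset so that noiseless backgrounds still separate
#' strictly.
#'
#' @param dys dystrophin channel matrix.
#' @param labels a `fiber_label_map` (its zero pixels define interstitium).
#' @return threshold in AU.
#' @export
auto_positivity_threshold <- function(dys, labels) {
  if (inherits(dys, "section_image")) dys <- dys$DYS
  bg <- dys[labels$labels == 0L]
  if (length(bg) < 100L) stopf("too few interstitial pixels for auto threshold")
  pixel_mode(bg) + 3 * stats::mad(bg) + 0.5
}

#' Circumference coverage of dystrophin per fiber
#'
#' Each of the K equal-angle arc segments of a ring is scored positive when
#' its mean dystrophin value reaches the positivity threshold. Arc segments
#' without ring pixels inherit the value of the nearest non-empty segment
#' (circularly). A circular majority filter of window `w` suppresses
#' single-segment flips before counting. Coverage is 100 * positive/K.
#'
#' @param dys dystrophin channel matrix or `section_image`.
#' @param rings a `sarcolemmal_rings` object.
#' @param positivity_threshold AU, or `"auto"` (requires `labels`).
#' @param labels `fiber_label_map`, needed when the threshold is `"auto"`.
#' @param w odd majority-smoothing window in arc segments (default 3).
#' @return named numeric vector of coverage percentages in \[0, 100\].
#' @export
measure_coverage <- function(dys, rings, positivity_threshold = "auto",
                             labels = NULL, w = 3L) {
  if (inherits(dys, "section_image")) dys <- dys$DYS
  stopifnot(inherits(rings, "sarcolemmal_rings"))
  if (identical(positivity_threshold, "auto")) {
    if (is.null(labels)) stopf("auto positivity threshold requires `labels`")
    thr <- auto_positivity_threshold(dys, labels)
  } else {
    thr <- as.numeric(positivity_threshold)
    if (thr > MAX_AU) stopf("positivity threshold exceeds the 16-bit range")
  }
  K <- rings$K
  px <- rings$pixels
  val <- dys[cbind(px$r, px$c)]
  dt <- data.table::data.table(fiber_id = px$fiber_id, arc = px$arc, v = val)
  arc_means <- dt[, list(m = mean(v)), by = c("fiber_id", "arc")]
  by_fiber <- split(arc_means, arc_means$fiber_id)
  ids <- sort(unique(px$fiber_id))
  out <- vapply(ids, function(id) {
    am <- by_fiber[[as.character(id)]]
    m <- rep(NA_real_, K)
    m[am$arc] <- am$m
    # majority-smooth over the measured (non-empty) arc sequence first, then
    # let empty segments inherit the nearest smoothed decision: smoothing in
    # the measurement domain keeps single-pixel noise flips from being
    # amplified through the interpolation
    ne <- which(!is.na(m))
    pos_ne <- majority_smooth(m[ne] >= thr, w)
    pos <- rep(NA, K)
    pos[ne] <- pos_ne
    pos <- fill_circular(pos) > 0
    100 * mean(pos)
  }, numeric(1))
  names(out) <- ids
  attr(out, "threshold") <- thr
  out
}

# nearest-neighbour circular fill of NA entries
fill_circular <- function(m) {
  na <- which(is.na(m))
  if (length(na) == 0L) return(m)
  ok <- which(!is.na(m))
  if (length(ok) == 0L) stopf("empty sarcolemmal ring")
  K <- length(m)
  for (i in na) {
    d <- abs(ok - i)
    d <- pmin(d, K - d)
    m[i] <- m[ok[which.min(d)]]
  }
  m
}

# circular majority filter over a logical vector, window w (odd)
majority_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  K <- length(x)
  half <- (w - 1L) %/% 2L
  acc <- integer(K)
  for (s in -half:half) acc <- acc + x[((seq_len(K) - 1L + s) %% K) + 1L]
  acc > w / 2
}

#' Classify a fiber as dystrophin-positive
#'
#' A fiber is positive when its circumference coverage is 25\% or more.
#'
#' @param coverage coverage percentage(s) in \[0, 100\].
#' @return logical vector.
#' @export
classify_positive <- function(coverage) {
  if (any(coverage < 0 | coverage > 100 | is.na(coverage))) {
    stopf("coverage must lie in [0, 100]")
  }
  coverage >= 25
}

#' Assign the coverage bin of a fiber
#'
#' Bins are half-open: B1 = \[0,25), B2 = \[25,50), B3 = \[50,75),
#' B4 = \[75,100\]. Under this convention a fiber is dystrophin-positive
#' exactly when it is not in B1.
#'
#' @param coverage coverage percentage(s) in \[0, 100\].
#' @return factor with levels B1..B4.
#' @export
assign_bin <- function(coverage) {
  if (any(coverage < 0 | coverage > 100 | is.na(coverage))) {
    stopf("coverage must lie in [0, 100]")
  }
  idx <- 1L + findInterval(coverage, c(25, 50, 75))
  factor(COVERAGE_BINS[idx], levels = COVERAGE_BINS)
}

#' Quantify all fibers of a two-channel section
#'
#' Runs segmentation, ring extraction, and per-fiber intensity and coverage
#' measurement; the one-stop per-section entry point.
#'
#' @param image a `section_image`.
#' @param min_area,laminin_threshold passed to [segment_fibers()].
#' @param ring_width,K passed to [extract_ring()].
#' @param positivity_threshold,w passed to [measure_coverage()].
#' @return data.frame of fiber records: fiber_id, cx, cy, area_px,
#'   mean_intensity_au, coverage_pct, positive, bin; segmentation metadata
#'   (thresholds, exclusions) as attribute `meta`.
#' @export
quantify_fibers <- function(image, min_area = 100L, laminin_threshold = "auto",
                            ring_width = 3L, K = 360L,
                            positivity_threshold = "auto", w = 3L) {
  stopifnot(inherits(image, "section_image"))
  labels <- segment_fibers(image$LAMA2, min_area = min_area,
                           laminin_threshold = laminin_threshold,
                           grow_iters = ring_width + 3L)
  if (labels$n_fibers == 0L) stopf("no fibers segmented")
  rings <- extract_ring(labels, ring_width = ring_width, K = K)
  intensity <- measure_intensity(image$DYS, rings)
  coverage <- measure_coverage(image$DYS, rings,
                               positivity_threshold = positivity_threshold,
                               labels = labels, w = w)
  ids <- labels$centroids$fiber_id
  rec <- data.frame(
    fiber_id = ids,
    cx = labels$centroids$cc,
    cy = labels$centroids$cr,
    area_px = labels$sizes[ids],
    mean_intensity_au = as.numeric(intensity[as.character(ids)]),
    coverage_pct = as.numeric(coverage[as.character(ids)]),
    row.names = NULL)
  rec$positive <- classify_positive(rec$coverage_pct)
  rec$bin <- assign_bin(rec$coverage_pct)
  attr(rec, "meta") <- list(
    laminin_threshold = labels$threshold,
    positivity_threshold = attr(coverage, "threshold"),
    n_excluded_border = labels$meta$n_excluded_border,
    n_excluded_small = labels$meta$n_excluded_small,
    whole_fiber_flags = sum(rings$whole_fiber))
  rec
}
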