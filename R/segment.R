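# Myofiber instance segmentation from the laminin-alpha-2 mask stain.
#
# Strategy: binarize the laminin network (Otsu by default), take connected
# components of the complement as fiber interiors, discard components that
# touch the image border (partial fiber profiles) or fall under min_area,
# then grow each label back over its own laminin band so the fiber region
# includes the sarcolemma the mask stain delineates.

#' Segment transverse myofibers from the laminin channel
#'
#' @param laminin single-channel 16-bit image (integer/numeric matrix) or a
#'   `section_image` (its `LAMA2` channel is used).
#' @param min_area minimum interior area in pixels; smaller components are
#'   treated as debris and discarded (default 100).
#' @param laminin_threshold AU threshold for the laminin network, or
#'   `"auto"` for Otsu on the channel.
#' @param grow_iters how far (pixels) labels may grow outward across the
#'   laminin band; should be at least the expected band width (default 6).
#' @return object of class `fiber_label_map`: `labels` (integer matrix,
#'   0 = background), `sizes`, `centroids` (fiber_id, cr, cc), `boundaries`
#'   (list of boundary pixel matrices ordered by angle around the
#'   centroid), `threshold`, and exclusion counts in `meta`.
#' @export
segment_fibers <- function(laminin, min_area = 100L,
                           laminin_threshold = "auto", grow_iters = 6L) {
  if (inherits(laminin, "section_image")) laminin <- laminin$LAMA2
  stopifnot(is.matrix(laminin))
  thr <- if (identical(laminin_threshold, "auto")) {
    otsu_threshold(laminin)
  } else {
    as.numeric(laminin_threshold)
  }
  H <- nrow(laminin); W <- ncol(laminin)
  network <- laminin >= thr
  if (all(network) || !any(network)) {
    stop("no fibers segmented: laminin network not found", call. = FALSE)
  }
  comp <- .label_components(!network)
  ncomp <- max(comp)
  if (ncomp == 0L) stop("no fibers segmented", call. = FALSE)
  border_ids <- unique(c(comp[1, ], comp[H, ], comp[, 1], comp[, W]))
  border_ids <- setdiff(border_ids, 0L)
  sizes <- tabulate(comp, ncomp)
  small_ids <- setdiff(which(sizes < min_area), border_ids)
  drop <- c(border_ids, small_ids)
  keep <- setdiff(seq_len(ncomp), drop)
  if (length(keep) == 0L) {
    lab <- matrix(0L, H, W)
    return(new_fiber_label_map(lab, thr, n_border = length(border_ids),
                               n_small = length(small_ids)))
  }
  remap <- integer(ncomp)
  remap[keep] <- seq_along(keep)
  lab <- matrix(0L, H, W)
  sel <- comp > 0L & remap[pmax(comp, 1L)] > 0L
  lab[sel] <- remap[comp[sel]]
  # claim the surrounding laminin band for each interior
  lab <- .grow_labels(lab, network, as.integer(grow_iters))
  new_fiber_label_map(lab, thr, n_border = length(border_ids),
                      n_small = length(small_ids))
}

new_fiber_label_map <- function(lab, thr, n_border = 0L, n_small = 0L) {
  n <- max(lab, 0L)
  sizes <- if (n > 0) tabulate(lab, n) else integer(0)
  centroids <- boundaries <- NULL
  if (n > 0) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    ids <- lab[idx]
    cr <- tapply(idx[, 1], ids, mean)
    cc <- tapply(idx[, 2], ids, mean)
    centroids <- data.frame(fiber_id = as.integer(names(cr)),
                            cr = as.numeric(cr), cc = as.numeric(cc))
    inner <- .peel_labels(lab, 1L, FALSE)
    bsel <- inner[idx] == 0L
    bidx <- idx[bsel, , drop = FALSE]
    bids <- ids[bsel]
    boundaries <- lapply(seq_len(n), function(i) {
      b <- bidx[bids == i, , drop = FALSE]
      th <- pixel_angle(b[, 1], b[, 2], centroids$cr[i], centroids$cc[i])
      b[order(th), , drop = FALSE]
    })
  }
  structure(list(labels = lab, n_fibers = n, sizes = sizes,
                 centroids = centroids, boundaries = boundaries,
                 threshold = thr,
                 meta = list(n_excluded_border = n_border,
                             n_excluded_small = n_small)),
            class = "fiber_label_map")
}

#' @export
print.fiber_label_map <- function(x, ...) {
  cat(sprintf(
    "<fiber_label_map> %d fibers (excluded: %d border, %d small), laminin threshold %.1f AU\n",
    x$n_fibers, x$meta$n_excluded_border, x$meta$n_excluded_small, x$threshold))
  invisible(x)
}

#' Extract the sarcolemmal ring of every segmented fiber
#'
#' The ring is the morphological inner band of `ring_width` pixels from each
#' fiber's boundary. Ring pixels are parameterized into `K` equal-angle arc
#' segments around the fiber centroid (the resolution at which circumference
#' coverage is later scored). Fibers too small to support the band keep
#' their whole region as the ring and are flagged.
#'
#' @param labels a `fiber_label_map`.
#' @param ring_width band width in pixels (>= 1).
#' @param K number of equal-angle arc segments (default 360, i.e. 1 degree).
#' @return object of class `sarcolemmal_rings`: `pixels` (data.table with
#'   fiber_id, r, c, arc), `K`, `centroids`, and `whole_fiber` flags.
#' @export
extract_ring <- function(labels, ring_width = 3L, K = 360L) {
  stopifnot(inherits(labels, "fiber_label_map"), ring_width >= 1, K >= 4)
  lab <- labels$labels
  n <- labels$n_fibers
  if (n == 0L) stopf("label map contains no fibers")
  inner <- .peel_labels(lab, as.integer(ring_width), FALSE)
  idx <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[idx]
  in_ring <- inner[idx] == 0L
  # fibers fully consumed by the band keep the whole region, flagged
  ring_count <- tabulate(ids[in_ring], n)
  whole <- tabulate(ids, n) == ring_count
  use <- in_ring | whole[ids]
  px <- data.table::data.table(fiber_id = ids[use],
                               r = idx[use, 1], c = idx[use, 2])
  cen <- labels$centroids
  px <- merge(px, data.table::as.data.table(cen), by = "fiber_id", sort = TRUE)
  theta <- pixel_angle(px$r, px$c, px$cr, px$cc)
  px[, c("arc", "cr", "cc") := list(
    1L + as.integer(pmin(K - 1L, floor(theta / (2 * pi) * K))), NULL, NULL)]
  structure(list(pixels = px, K = as.integer(K), centroids = cen,
                 ring_width = as.integer(ring_width),
                 whole_fiber = whole, n_fibers = n),
            class = "sarcolemmal_rings")
}

#' @export
print.sarcolemmal_rings <- function(x, ...) {
  cat(sprintf("<sarcolemmal_rings> %d fibers, width %d px, K = %d arcs, %d flagged whole-fiber\n",
              x$n_fibers, x$ring_width, x$K, sum(x$whole_fiber)))
  invisible(x)
}
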