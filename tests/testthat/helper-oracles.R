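# Independent oracles and small fixture builders used across the suite.

# Exact Mann-Whitney two-sided p by full enumeration of group labelings:
# 2 * P(U <= min(Ux, Uy)) over all C(n1+n2, n1) assignments.
enum_mw_p <- function(xs, ys) {
  pooled <- c(xs, ys)
  n1 <- length(xs)
  N <- length(pooled)
  u_obs <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_min <- min(u_obs, n1 * (N - n1) - u_obs)
  us <- apply(utils::combn(N, n1), 2, function(ix) {
    sum(outer(pooled[ix], pooled[-ix], ">"))
  })
  min(1, 2 * mean(us <= u_min))
}

# Area of intersection of two convex polygons (Sutherland-Hodgman clipping
# + shoelace). Polygons are (r, c) matrices, open (no repeated last vertex).
convex_intersection_area <- function(p, q) {
  clip_edge <- function(poly, a, b) {
    if (nrow(poly) == 0) return(poly)
    # keep points left of edge a->b (for ccw clip polygon)
    side <- function(pt) (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
    out <- NULL
    n <- nrow(poly)
    for (i in seq_len(n)) {
      cur <- poly[i, ]; prv <- poly[if (i == 1) n else i - 1, ]
      sc <- side(cur); sp <- side(prv)
      if (sc >= 0) {
        if (sp < 0) {
          t <- sp / (sp - sc)
          out <- rbind(out, prv + t * (cur - prv))
        }
        out <- rbind(out, cur)
      } else if (sp >= 0) {
        t <- sp / (sp - sc)
        out <- rbind(out, prv + t * (cur - prv))
      }
    }
    if (is.null(out)) matrix(numeric(0), 0, 2) else out
  }
  ccw <- function(poly) {
    a <- shoelace_signed(poly)
    if (a < 0) poly[rev(seq_len(nrow(poly))), ] else poly
  }
  p <- ccw(p); q <- ccw(q)
  n <- nrow(q)
  for (i in seq_len(n)) {
    p <- clip_edge(p, q[i, ], q[if (i == n) 1 else i + 1, ])
    if (nrow(p) == 0) return(0)
  }
  abs(shoelace_signed(p))
}

shoelace_signed <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  sum(poly[j, 1] * poly[, 2] - poly[, 1] * poly[j, 2]) / 2
}

# strip the closing vertex a dysquant polygon carries
open_polygon <- function(poly) poly[-nrow(poly), , drop = FALSE]

# match measured fiber records to simulator ground truth by nearest centroid
match_ground_truth <- function(truth, records) {
  idx <- vapply(seq_len(nrow(records)), function(i) {
    which.min((truth$cx - records$cx[i])^2 + (truth$cy - records$cy[i])^2)
  }, integer(1))
  cbind(records, truth[idx, c("true_coverage", "true_intensity"),
                       drop = FALSE])
}

# a synthetic section with every fiber at full coverage and given intensity
full_coverage_section <- function(n_fibers, intensities, config, seed = 3,
                                  gap = 3) {
  geo <- generate_geometry(n_fibers, config$image_size, gap = gap, seed = seed)
  for (i in seq_along(geo)) {
    geo[[i]]$true_coverage <- 1
    geo[[i]]$true_intensity <- intensities[(i - 1) %% length(intensities) + 1]
    geo[[i]]$arc_phase <- 0
  }
  render_section(geo, config)
}

# one hand-built disk fiber rendered directly into a section_image
disk_section <- function(radius = 20, ring_width = 3, size = 64,
                         coverage = 1, intensity = 40000, phase = 0,
                         background = 800, lam_intensity = 30000) {
  theta <- seq(0, 2 * pi, length.out = 120)[-1]
  centre <- (size + 1) / 2
  poly <- cbind(r = centre + radius * sin(theta),
                c = centre + radius * cos(theta))
  fib <- list(list(fiber_id = 1L, polygon = rbind(poly, poly[1, ]),
                   true_coverage = coverage, true_intensity = intensity,
                   arc_phase = phase))
  cfg <- render_config(image_size = c(size, size), ring_width = ring_width,
                       laminin_intensity = lam_intensity,
                       background_level = background,
                       noise_sd = 0, blur_sigma = 0, seed = 1)
  render_section(fib, cfg)
}
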