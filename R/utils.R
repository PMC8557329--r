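# Internal helpers shared across modules.

# Run `expr` under a local RNG stream; the caller's global RNG state is
# untouched. All exported stochastic operations route randomness through this.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

MAX_AU <- 65535L

clamp16 <- function(x) pmin(pmax(x, 0), MAX_AU)

#' Otsu threshold of a single-channel image
#'
#' Maximizes between-class variance over a 256-bin histogram of the pixel
#' values. Used as the default binarization of the laminin mask stain.
#'
#' @param x numeric matrix or vector of pixel values.
#' @return threshold on the intensity scale of `x`.
#' @keywords internal
otsu_threshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    stop("no fibers segmented: image is flat", call. = FALSE)
  }
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((x - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# Separable Gaussian blur with edge replication. sigma = 0 is the identity.
blur_gaussian <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  R <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-R:R)^2) / (2 * sigma^2))
  k <- k / sum(k)
  H <- nrow(mat); W <- ncol(mat)
  out <- matrix(0, H, W)
  for (i in -R:R) {
    out <- out + k[i + R + 1L] * mat[pmin(pmax(seq_len(H) + i, 1L), H), , drop = FALSE]
  }
  out2 <- matrix(0, H, W)
  for (i in -R:R) {
    out2 <- out2 + k[i + R + 1L] * out[, pmin(pmax(seq_len(W) + i, 1L), W), drop = FALSE]
  }
  out2
}

# Even-odd rule point-in-polygon for pixel centres of the polygon's bounding
# box. `poly` is a matrix with columns (r, c); returns a 2-column matrix of
# inside pixel coordinates.
rasterize_polygon <- function(poly, H, W) {
  pr <- poly[, 1]; pc <- poly[, 2]
  rs <- max(1L, floor(min(pr))):min(H, ceiling(max(pr)))
  cs <- max(1L, floor(min(pc))):min(W, ceiling(max(pc)))
  grid_r <- rep(rs, times = length(cs))
  grid_c <- rep(cs, each = length(rs))
  inside <- rep(FALSE, length(grid_r))
  n <- length(pr)
  j <- n
  for (i in seq_len(n)) {
    crossing <- ((pr[i] > grid_r) != (pr[j] > grid_r))
    if (any(crossing)) {
      xin <- (pc[j] - pc[i]) * (grid_r[crossing] - pr[i]) /
        (pr[j] - pr[i]) + pc[i]
      flip <- grid_c[crossing] < xin
      inside[crossing][flip] <- !inside[crossing][flip]
    }
    j <- i
  }
  cbind(r = grid_r[inside], c = grid_c[inside])
}

# Mode of a (large, noisy) pixel sample via kernel density; used by the
# "auto" positivity threshold to locate the interstitial background level.
pixel_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

# angle of pixels around a centre, in [0, 2*pi)
pixel_angle <- function(r, c, cr, cc) {
  (atan2(r - cr, c - cc) + 2 * pi) %% (2 * pi)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
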