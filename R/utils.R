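# Internal helpers shared across modules.

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of their spec.
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Separable Gaussian convolution with edge replication; kernel truncated at
# 4 sigma. Used for the synthetic PSF; sigma in pixels.
gaussian_blur <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  rad <- as.integer(ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-rad, rad), sd = sigma_px)
  k <- k / sum(k)
  x <- .conv_dim(x, k, 1L)
  .conv_dim(x, k, 2L)
}

.conv_dim <- function(x, k, dim) {
  rad <- (length(k) - 1L) %/% 2L
  n <- if (dim == 1L) nrow(x) else ncol(x)
  out <- matrix(0, nrow(x), ncol(x))
  for (o in seq(-rad, rad)) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    w <- k[o + rad + 1L]
    out <- out + if (dim == 1L) w * x[idx, , drop = FALSE] else
      w * x[, idx, drop = FALSE]
  }
  out
}

# Otsu's threshold on a 256-bin histogram (maximum between-class variance).
# Returns a value on the intensity scale of `x`.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, edges, all.inside = TRUE), n_bins)
  p <- h / sum(h)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  centers[which.max(between)]
}

# Vectorised bilinear interpolation at (row, col); coordinates are 1-based
# pixel centers. Out-of-image points return NA.
bilinear_interp <- function(plane, row, col) {
  nr <- nrow(plane); nc <- ncol(plane)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  r0 <- pmin(pmax(floor(row), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(col), 1L), nc - 1L)
  fr <- row - r0
  fc <- col - c0
  v <- plane[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    plane[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    plane[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    plane[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  v[!ok] <- NA_real_
  v
}

# Catmull-Rom weights for the four support points at offsets -1, 0, 1, 2
# around the interpolation cell, fraction f in [0, 1).
.catmull_rom_w <- function(f) {
  cbind(((-0.5 * f + 1) * f - 0.5) * f,
        (1.5 * f - 2.5) * f * f + 1,
        ((-1.5 * f + 2) * f + 0.5) * f,
        (0.5 * f - 0.5) * f * f)
}

# Vectorised bicubic (Catmull-Rom) interpolation; support clamped at the
# image edge. Out-of-image points return NA.
bicubic_interp <- function(plane, row, col) {
  nr <- nrow(plane); nc <- ncol(plane)
  ok <- row >= 1 & row <= nr & col >= 1 & col <= nc
  r0 <- floor(row); c0 <- floor(col)
  wr <- .catmull_rom_w(row - r0)
  wc <- .catmull_rom_w(col - c0)
  out <- numeric(length(row))
  for (i in 1:4) {
    ri <- pmin(pmax(r0 + i - 2L, 1L), nr)
    for (j in 1:4) {
      cj <- pmin(pmax(c0 + j - 2L, 1L), nc)
      out <- out + wr[, i] * wc[, j] * plane[cbind(ri, cj)]
    }
  }
  out[!ok] <- NA_real_
  out
}

interp_plane <- function(plane, row, col, method = c("cubic", "bilinear")) {
  method <- match.arg(method)
  if (method == "cubic") bicubic_interp(plane, row, col)
  else bilinear_interp(plane, row, col)
}
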