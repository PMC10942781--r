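# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs `code` on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Full width at half maximum of a sampled profile
#'
#' Locates the global maximum of `y` and the two half-maximum crossings on
#' either side by linear interpolation between samples, after subtracting a
#' baseline. Sub-grid accuracy therefore depends only on local linearity of
#' the profile near the half-max level, not on the grid pitch.
#'
#' @param x sample positions (monotone increasing).
#' @param y sampled values, same length as `x`.
#' @param baseline value subtracted before normalization (default 0).
#' @return list with `fwhm`, `left`, `right` (crossing positions) and `peak`
#'   (position of the maximum sample). `fwhm` is `NA` when a crossing does not
#'   exist inside the sampled support.
#' @export
fwhm_profile <- function(x, y, baseline = 0) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  y <- y - baseline
  ipk <- which.max(y)
  ymax <- y[ipk]
  if (!is.finite(ymax) || ymax <= 0) {
    return(list(fwhm = NA_real_, left = NA_real_, right = NA_real_, peak = x[ipk]))
  }
  half <- ymax / 2
  left <- NA_real_
  if (ipk >= 2L) for (i in seq(ipk, 2L)) {
    if (y[i - 1L] < half && y[i] >= half) {
      left <- x[i - 1L] + (x[i] - x[i - 1L]) * (half - y[i - 1L]) / (y[i] - y[i - 1L])
      break
    }
  }
  right <- NA_real_
  n <- length(y)
  if (ipk < n) {
    for (i in seq(ipk, n - 1L)) {
      if (y[i] >= half && y[i + 1L] < half) {
        right <- x[i] + (x[i + 1L] - x[i]) * (y[i] - half) / (y[i] - y[i + 1L])
        break
      }
    }
  }
  list(fwhm = right - left, left = left, right = right, peak = x[ipk])
}

# Gaussian kernel sampled on integer offsets, truncated at `radius` and
# renormalized to unit sum. sigma in sample units.
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 1-D convolution of a matrix along rows (dim = 1) or columns
# (dim = 2) with zero padding at the borders.
convolve_dim <- function(m, kernel, dim = 1L) {
  nk <- length(kernel)
  if (nk == 1L) return(m * kernel)
  r <- (nk - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(nk)) {
    off <- j - r - 1L
    if (dim == 1L) {
      src <- seq_len(nrow(m)) + off
      ok <- src >= 1L & src <= nrow(m)
      out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], ]
    } else {
      src <- seq_len(ncol(m)) + off
      ok <- src >= 1L & src <= ncol(m)
      out[, ok] <- out[, ok] + kernel[j] * m[, src[ok]]
    }
  }
  out
}

# Isotropic Gaussian blur of a 3-D array, separable per axis; sigma in voxels
# (scalar or length-3). Zero padding.
blur3d <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3L)
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gaussian_kernel(sigma[ax])
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    m <- convolve_dim(m, k, dim = 1L)
    b <- array(m, db)
    a <- aperm(b, order(perm))
  }
  a
}

# Trilinear sampling of a 3-D array at fractional 0-based voxel coordinates.
# Points outside the grid return `fill`.
trilinear_sample <- function(a, xs, ys, zs, fill = 0) {
  d <- dim(a)
  out <- rep(fill, length(xs))
  inside <- xs >= 0 & xs <= d[1] - 1 & ys >= 0 & ys <= d[2] - 1 & zs >= 0 & zs <= d[3] - 1
  if (!any(inside)) return(out)
  x <- xs[inside]; y <- ys[inside]; z <- zs[inside]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2); z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  i0 <- x0 + 1L; j0 <- y0 + 1L; k0 <- z0 + 1L
  idx <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  v <- a[idx(i0,     j0,     k0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
       a[idx(i0 + 1, j0,     k0)]     * fx       * (1 - fy) * (1 - fz) +
       a[idx(i0,     j0 + 1, k0)]     * (1 - fx) * fy       * (1 - fz) +
       a[idx(i0 + 1, j0 + 1, k0)]     * fx       * fy       * (1 - fz) +
       a[idx(i0,     j0,     k0 + 1)] * (1 - fx) * (1 - fy) * fz +
       a[idx(i0 + 1, j0,     k0 + 1)] * fx       * (1 - fy) * fz +
       a[idx(i0,     j0 + 1, k0 + 1)] * (1 - fx) * fy       * fz +
       a[idx(i0 + 1, j0 + 1, k0 + 1)] * fx       * fy       * fz
  out[inside] <- v
  out
}

stop_domain <- function(...) stop(..., call. = FALSE)
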