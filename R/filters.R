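#' @useDynLib salgaze, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' 2-D linear filtering with zero padding
#'
#' Cross-correlates an image with a kernel, keeping the image size and
#' treating pixels outside the image as zero. This is the single filtering
#' primitive behind every channel, pyramid and activation stage, so the
#' whole model can be checked against a naive dense-convolution oracle.
#'
#' @param x numeric matrix (image).
#' @param k numeric matrix (kernel, odd-sized in both dimensions).
#' @param pad `"replicate"` (default) extends edge pixels outward, so
#'   zero-mean kernels respond with exact zeros on constant images;
#'   `"zero"` treats the outside as black.
#' @return numeric matrix of the same size as `x`.
#' @export
filter2d <- function(x, k, pad = "replicate") {
  if (pad == "replicate") {
    conv2d_same(x, k, 1L)
  } else if (pad == "zero") {
    conv2d_same(x, k, 0L)
  } else {
    stop("pad must be \"replicate\" or \"zero\"")
  }
}

#' Gaussian kernel
#'
#' @param sigma standard deviation in pixels.
#' @param size odd kernel side; default covers +/- 3 sigma.
#' @return normalised (unit-sum) square kernel.
#' @export
gaussian_kernel <- function(sigma, size = NULL) {
  stopifnot(sigma > 0)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  stopifnot(size %% 2L == 1L)
  r <- (size - 1L) / 2
  d <- seq(-r, r)
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Laplacian-of-Gaussian ("Mexican hat") kernel
#'
#' Center-positive convention (the negated Laplacian), so a bright spot
#' on a dark surround responds positively at its center — the polarity
#' the half-wave-rectified center-surround cascade needs. Zero-mean, so
#' a constant image maps to an exactly zero response.
#'
#' @inheritParams gaussian_kernel
#' @export
log_kernel <- function(sigma, size = NULL) {
  stopifnot(sigma > 0)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  stopifnot(size %% 2L == 1L)
  r <- (size - 1L) / 2
  d <- seq(-r, r)
  xx <- outer(d^0, d^2)  # column offsets squared, by row
  yy <- outer(d^2, d^0)
  s2 <- sigma^2
  k <- -(xx + yy - 2 * s2) / (s2 * s2) * exp(-(xx + yy) / (2 * s2))
  k - mean(k)  # enforce exact zero DC response
}

#' Quadrature Gabor kernel pair
#'
#' @param theta orientation in radians (0 = horizontal carrier variation).
#' @param wavelength carrier wavelength in pixels.
#' @param sigma Gaussian envelope sd in pixels (default wavelength / 2).
#' @param size odd kernel side.
#' @return list with `even` (cosine, zero-mean) and `odd` (sine) kernels.
#' @export
gabor_kernel <- function(theta, wavelength, sigma = wavelength / 2,
                         size = NULL) {
  stopifnot(wavelength > 0, sigma > 0)
  if (is.null(size)) size <- 2L * ceiling(2.5 * sigma) + 1L
  stopifnot(size %% 2L == 1L)
  r <- (size - 1L) / 2
  d <- seq(-r, r)
  yy <- matrix(d, size, size)        # row offsets
  xx <- matrix(d, size, size, byrow = TRUE)  # column offsets
  xr <- xx * cos(theta) + yy * sin(theta)
  env <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
  ph <- 2 * pi * xr / wavelength
  even <- env * cos(ph)
  even <- even - mean(even)
  odd <- env * sin(ph)
  list(even = even, odd = odd)
}

# Decimate by two, keeping rows/columns 1, 3, 5, ... so an n-pixel side
# becomes ceiling(n / 2): 75 -> 38 -> 19 -> 10.
decimate2 <- function(x) {
  x[seq(1L, nrow(x), by = 2L), seq(1L, ncol(x), by = 2L), drop = FALSE]
}

# Bilinear resize with corner alignment; degenerate 1-pixel sources are
# broadcast.
resize_bilinear <- function(x, nr, nc) {
  sr <- nrow(x)
  sc <- ncol(x)
  map_axis <- function(n_out, n_src) {
    if (n_src == 1L) {
      list(lo = rep(1L, n_out), hi = rep(1L, n_out), w = rep(0, n_out))
    } else {
      pos <- seq(0, n_src - 1L, length.out = n_out)
      lo <- pmin(floor(pos), n_src - 2)
      list(lo = as.integer(lo) + 1L, hi = as.integer(lo) + 2L, w = pos - lo)
    }
  }
  ri <- map_axis(nr, sr)
  ci <- map_axis(nc, sc)
  a <- x[ri$lo, ci$lo, drop = FALSE]
  b <- x[ri$hi, ci$lo, drop = FALSE]
  cc <- x[ri$lo, ci$hi, drop = FALSE]
  d <- x[ri$hi, ci$hi, drop = FALSE]
  wr <- matrix(ri$w, nr, nc)
  wc <- matrix(ci$w, nr, nc, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc +
    d * wr * wc
}
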