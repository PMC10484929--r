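# Separable Gaussian filtering implemented as banded matrix products.
# Kernels are truncated at 4 sigma and renormalised row-wise, so a constant
# image maps exactly to itself (including at the borders); this is the
# property the DC-removing high-pass relies on.

gauss_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n one-dimensional blur operator with renormalised truncation at edges.
blur_operator <- function(n, sigma) {
  radius <- ceiling(4 * sigma)
  k <- gauss_kernel_1d(sigma, radius)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - radius):(i + radius)
    keep <- j >= 1 & j <= n
    w <- k[keep]
    m[i, j[keep]] <- w / sum(w)
  }
  m
}

#' 2D Gaussian blur of a matrix (separable, truncated at 4 sigma)
#' @keywords internal
gblur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  ky <- blur_operator(nrow(img), sigma)
  kx <- blur_operator(ncol(img), sigma)
  ky %*% img %*% t(kx)
}

# Slicewise (per z-plane) in-plane Gaussian blur of a (y, x, z) volume.
# Vectorised: one matrix product per axis covers all slices.
gblur_slicewise <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  ky <- blur_operator(d[1], sigma)
  v <- array(ky %*% matrix(vol, d[1]), dim = d)
  v <- aperm(v, c(2, 1, 3))
  kx <- blur_operator(d[2], sigma)
  v <- array(kx %*% matrix(v, d[2]), dim = d[c(2, 1, 3)])
  aperm(v, c(2, 1, 3))
}

# Binary disk kernel of given pixel radius (odd-sized matrix).
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  x <- seq(-r, r)
  d2 <- outer(x^2, x^2, "+")
  k <- (d2 <= r^2) * 1
  k
}

# Mean over a disk neighbourhood, replicate boundary (FFT via EBImage).
local_mean_disk <- function(img, radius) {
  k <- disk_kernel(radius)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}
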