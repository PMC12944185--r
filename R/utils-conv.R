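# Separable 3D convolution with symmetric (half-sample reflected) boundary
# handling, used by the wavelet filter bank and the phantom's correlated
# noise fields. Implemented as a banded matrix product per axis so that a
# whole volume is filtered with three matrix multiplications.

# map out-of-range index p (0-based, may be negative or >= n) to a valid
# 0-based index under half-sample symmetric reflection: ... 2 1 0 | 0 1 2 ...
.reflectIndex <- function(p, n) {
  if (n == 1L) return(rep(0L, length(p)))
  period <- 2L * n
  p <- p %% period
  ifelse(p < n, p, period - 1L - p)
}

# n x n dense operator applying 1D correlation with `kernel`; output[i] =
# sum_k kernel[k] * x[reflect(i + k - shift)], shift = floor(len/2) (0-based).
.convMatrix <- function(n, kernel) {
  len <- length(kernel)
  shift <- len %/% 2L
  M <- matrix(0, n, n)
  for (k in seq_len(len)) {
    src <- .reflectIndex(seq_len(n) - 1L + (k - 1L) - shift, n) + 1L
    M[cbind(seq_len(n), src)] <- M[cbind(seq_len(n), src)] + kernel[k]
  }
  M
}

# apply a 1D kernel along one axis of a 3D array (symmetric padding)
.convAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  M <- .convMatrix(d[axis], kernel)
  if (axis == 1L) {
    out <- M %*% matrix(arr, nrow = d[1])
  } else if (axis == 2L) {
    perm <- aperm(arr, c(2, 1, 3))
    out <- M %*% matrix(perm, nrow = d[2])
    return(aperm(array(out, dim = c(d[2], d[1], d[3])), c(2, 1, 3)))
  } else {
    perm <- aperm(arr, c(3, 1, 2))
    out <- M %*% matrix(perm, nrow = d[3])
    return(aperm(array(out, dim = c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  array(out, dim = d)
}

.gaussianKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# spatially correlated standard-normal field: Gaussian-filtered white noise
# rescaled to unit variance
.correlatedField <- function(dimv, sigma) {
  f <- array(stats::rnorm(prod(dimv)), dim = dimv)
  if (sigma > 0) {
    k <- .gaussianKernel(sigma)
    for (ax in 1:3) f <- .convAxis(f, k, ax)
    s <- stats::sd(as.vector(f))
    if (s > 0) f <- f / s
  }
  f
}
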