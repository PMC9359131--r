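#' @include AllClasses.R
NULL

# Separable 3-D Gaussian convolution on a plain array.
#
# sigmaVox is the Gaussian sd in voxel units per axis; axes with sigma 0 are
# left untouched. Edges use replicate (nearest) padding so constant regions
# are preserved exactly up to floating point. Kernel support is 4 sigma.
.gaussianKernel <- function(sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

.convolveAxis <- function(arr, k, axis) {
  d <- dim(arr)
  r <- (length(k) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1L]
  m <- matrix(a, nrow = n)
  # replicate padding: clamp shifted indices to [1, n]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(n) + (j - 1L - r), 1L), n)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  aperm(array(out, dim(a)), order(perm))
}

.gaussianBlur3D <- function(arr, sigmaVox) {
  for (axis in 1:3)
    if (sigmaVox[axis] > 0)
      arr <- .convolveAxis(arr, .gaussianKernel(sigmaVox[axis]), axis)
  arr
}
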