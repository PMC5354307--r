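## Gaussian kernels and zero-padded separable convolution.
##
## All smoothing in the package uses Gaussian kernels truncated at 3 sigma
## (or an explicit radius), renormalised to sum 1, applied with zero padding:
## outside the frame there is no tissue, so missing neighbours contribute
## nothing. Separable shift-and-add keeps this exact and fast.

#' Truncated, normalised 1-D Gaussian kernel
#' @param sigma standard deviation in pixels/voxels.
#' @param radius half-width; defaults to `ceiling(3 * sigma)` (minimum 1).
#' @return numeric vector of length `2 * radius + 1` summing to 1.
#' @export
gauss_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seqate(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

seqate <- function(a, b) seq.int(a, b)

## Shift a matrix by (dx, dy) pixels (positive = towards larger index),
## zero-filling. dx moves along dim 1 (x), dy along dim 2 (y).
shift_mat <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)) - dx
  ys <- seq_len(ncol(m)) - dy
  okx <- xs >= 1L & xs <= nrow(m)
  oky <- ys >= 1L & ys <= ncol(m)
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

shift_arr3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  xs <- seq_len(d[1]) - dx; ys <- seq_len(d[2]) - dy; zs <- seq_len(d[3]) - dz
  okx <- xs >= 1L & xs <= d[1]; oky <- ys >= 1L & ys <= d[2]; okz <- zs >= 1L & zs <= d[3]
  out[okx, oky, okz] <- a[xs[okx], ys[oky], zs[okz]]
  out
}

conv_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  out <- a * k[r + 1L]
  nd <- if (is.matrix(a)) 2L else 3L
  for (o in seq_len(r)) {
    if (nd == 2L) {
      if (axis == 1L) out <- out + k[r + 1L + o] * shift_mat(a, o, 0) + k[r + 1L - o] * shift_mat(a, -o, 0)
      else            out <- out + k[r + 1L + o] * shift_mat(a, 0, o) + k[r + 1L - o] * shift_mat(a, 0, -o)
    } else {
      sh <- c(0L, 0L, 0L); sh[axis] <- o
      out <- out + k[r + 1L + o] * shift_arr3(a, sh[1], sh[2], sh[3]) +
        k[r + 1L - o] * shift_arr3(a, -sh[1], -sh[2], -sh[3])
    }
  }
  out
}

#' Separable zero-padded Gaussian convolution
#'
#' @param a numeric matrix (2-D) or 3-D array.
#' @param sigma Gaussian standard deviation.
#' @param radius kernel half-width (default 3 sigma).
#' @return smoothed matrix/array of the same shape.
#' @export
gauss_smooth <- function(a, sigma, radius = max(1L, ceiling(3 * sigma))) {
  k <- gauss_kernel(sigma, radius)
  out <- conv_axis(a, k, 1L)
  out <- conv_axis(out, k, 2L)
  if (!is.matrix(a)) out <- conv_axis(out, k, 3L)
  out
}

## The separable product kernel over its square/cubic window, as an explicit
## array. Used by the brute-force double-sum oracles and the watershed caches.
gauss_kernel_nd <- function(sigma, nd, radius = max(1L, ceiling(3 * sigma))) {
  k <- gauss_kernel(sigma, radius)
  if (nd == 2L) outer(k, k) else {
    kk <- outer(k, k)
    array(outer(kk, k), dim = c(length(k), length(k), length(k)))
  }
}

## Block (window) means of a matrix with non-overlapping w x w windows;
## partial border windows keep their own mean. Returns a matrix of the same
## size as `m` holding each pixel's window mean.
block_mean_expand <- function(m, w) {
  bi <- (seq_len(nrow(m)) - 1L) %/% w
  bj <- (seq_len(ncol(m)) - 1L) %/% w
  sums <- rowsum(t(rowsum(m, bi)), bj)            # [bj, bi]
  cnt <- tabulate(bi + 1L) %o% tabulate(bj + 1L)  # [bi, bj]
  means <- t(sums) / cnt
  matrix(means[cbind(rep(bi + 1L, times = ncol(m)), rep(bj + 1L, each = nrow(m)))],
         nrow(m), ncol(m))
}
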