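# FFT helpers shared by the forward simulator, the unwrapper and the solvers.
# All spectral grids follow the usual DFT layout: frequency 0 at index 1,
# positive frequencies first, negative frequencies in the upper half.

#' DFT sample frequencies (cycles per sample)
#' @param n number of samples
#' @return numeric vector of length n
#' @keywords internal
fft_freq <- function(n) {
  if (n == 1L) return(0)
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

#' 3D FFT / inverse FFT
#' @param x numeric or complex 3D array
#' @return complex array of the same shape
#' @keywords internal
fft3 <- function(x) stats::fft(x)

#' @rdname fft3
#' @keywords internal
ifft3 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Zero-pad an array at the high-index end of each axis
#' @param x 3D array
#' @param shape target dimensions (each >= dim(x))
#' @param fill fill value for the padded region
#' @keywords internal
pad_to <- function(x, shape, fill = 0) {
  d <- dim(x)
  stopifnot(length(shape) == 3L, all(shape >= d))
  out <- array(fill, dim = shape)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

#' Crop an array back to the low-index corner
#' @param x 3D array
#' @param shape target dimensions (each <= dim(x))
#' @keywords internal
crop_to <- function(x, shape) {
  x[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
}

#' Mirror (reflect) an array to double size along every axis
#'
#' The even extension is continuous across the periodic boundary, which keeps
#' spectral differentiation of non-periodic volumes well behaved.
#' @param x 3D array
#' @keywords internal
mirror_pad <- function(x) {
  d <- dim(x)
  x <- x[c(seq_len(d[1]), rev(seq_len(d[1]))), , , drop = FALSE]
  x <- x[, c(seq_len(d[2]), rev(seq_len(d[2]))), , drop = FALSE]
  x[, , c(seq_len(d[3]), rev(seq_len(d[3]))), drop = FALSE]
}

#' Spectral Laplacian multiplier on a voxel-index grid
#'
#' Returns -(2 pi)^2 (kx^2 + ky^2 + kz^2) with k in cycles per voxel. Used in
#' matched forward/inverse pairs, so the (arbitrary) voxel-unit scale cancels.
#' @param shape grid dimensions
#' @keywords internal
laplace_multiplier <- function(shape) {
  kx <- fft_freq(shape[1]); ky <- fft_freq(shape[2]); kz <- fft_freq(shape[3])
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  -(2 * pi)^2 * k2
}

#' Extract one 3D volume from a 4D stack without dropping singleton axes
#' @param a 4D array
#' @param i index along the 4th axis
#' @keywords internal
slice4 <- function(a, i) {
  d <- dim(a)
  array(a[, , , i], dim = d[1:3])
}

#' Apply a k-space multiplier to a real volume
#' @param x real 3D array
#' @param mult k-space multiplier array, same shape
#' @return real array
#' @keywords internal
kspace_filter <- function(x, mult) {
  Re(ifft3(mult * fft3(x)))
}
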