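# Scalar free-space propagation by the band-limited angular spectrum method.
# All lengths (pitch, wavelength, distances) share one unit; by convention the
# examples in this package use units of the design wavelength.

#' Sampled complex optical field at a plane
#'
#' A `complex_field` holds a 2D grid of complex amplitudes together with its
#' lateral sampling interval (pitch), vacuum wavelength, and the refractive
#' index of the surrounding medium. The pitch defaults to `0.53 * wavelength`,
#' the diffraction-limited sampling used throughout the package.
#'
#' @param samples Complex (or numeric) matrix of field samples.
#' @param wavelength Vacuum wavelength, same length unit as `pitch`.
#' @param pitch Lateral sampling interval; default `0.53 * wavelength`.
#' @param medium_index Refractive index of the surrounding medium (>= 1).
#'   Propagation inside the medium uses the effective wavelength
#'   `wavelength / medium_index`.
#' @return An object of class `complex_field`.
#' @examples
#' f <- complex_field(matrix(1 + 0i, 8, 8), wavelength = 1)
#' @export
complex_field <- function(samples, wavelength, pitch = 0.53 * wavelength,
                          medium_index = 1) {
  if (!is.matrix(samples)) stop("'samples' must be a matrix")
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  if (nrow(samples) < 1L || ncol(samples) < 1L) stop("empty field grid")
  if (!is.finite(wavelength) || wavelength <= 0) stop("'wavelength' must be > 0")
  if (!is.finite(pitch) || pitch <= 0) stop("'pitch' must be > 0")
  if (!is.finite(medium_index) || medium_index < 1) stop("'medium_index' must be >= 1")
  structure(list(samples = samples, wavelength = wavelength, pitch = pitch,
                 medium_index = medium_index),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field %dx%d, pitch %.4g, wavelength %.4g, medium index %.4g>\n",
              nrow(x$samples), ncol(x$samples), x$pitch, x$wavelength, x$medium_index))
  invisible(x)
}

# DFT sample frequencies for an n-point grid with sample spacing d,
# in standard FFT layout: 0, 1/(n d), ..., then the negative branch.
fft_freq <- function(n, d) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

#' Angular-spectrum transfer function
#'
#' Free-space transfer function for propagation by a signed distance `distance`
#' at effective wavelength `wavelength` (i.e. the vacuum wavelength divided by
#' the medium index). Spatial frequencies with `fx^2 + fy^2 >= 1/wavelength^2`
#' are evanescent and return exactly 0; propagating components are pure phase
#' factors of unit modulus.
#'
#' @param fx,fy Spatial frequencies (cycles per length unit); recycled arrays.
#' @param distance Signed propagation distance.
#' @param wavelength Effective wavelength (> 0).
#' @return Complex array of transfer-function values.
#' @examples
#' asm_transfer_function(0, 0, distance = 2, wavelength = 1)  # exp(4i*pi)
#' @export
asm_transfer_function <- function(fx, fy, distance, wavelength) {
  if (!all(is.finite(fx)) || !all(is.finite(fy)))
    stop("non-finite spatial frequencies")
  if (!is.finite(distance)) stop("non-finite distance")
  if (!is.finite(wavelength) || wavelength <= 0) stop("'wavelength' must be > 0")
  arg <- 1 - (wavelength * fx)^2 - (wavelength * fy)^2
  H <- rep(0 + 0i, length(arg))
  prop <- arg > 0
  H[prop] <- exp(2i * pi * distance / wavelength * sqrt(arg[prop]))
  dim(H) <- dim(arg)
  H
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Propagate a sampled field by the angular spectrum method
#'
#' The field is zero-padded by an integer factor, transformed with the FFT,
#' multiplied by the band-limited transfer function and transformed back, then
#' cropped to the original grid. Negative distances back-propagate (conjugate
#' transfer function), which makes exact round trips possible for fields whose
#' spectrum lies inside the propagating band.
#'
#' The padded frequency grid has spacing `1/(n_pad * pitch)` in the standard
#' DFT layout. `pad_factor = 1` performs a periodic (unpadded) propagation.
#'
#' @param field A [complex_field].
#' @param distance Signed axial distance; 0 returns the field unchanged up to
#'   round-off.
#' @param pad_factor Integer >= 1 zero-padding factor (default 2).
#' @return A [complex_field] at the new plane; grid, pitch and wavelength are
#'   unchanged.
#' @examples
#' f <- complex_field(matrix(1 + 0i, 8, 8), wavelength = 1)
#' g <- propagate(f, distance = 3, pad_factor = 1)
#' @export
propagate <- function(field, distance, pad_factor = 2L) {
  stopifnot(inherits(field, "complex_field"))
  pad_factor <- as.integer(pad_factor)
  if (is.na(pad_factor) || pad_factor < 1L) stop("'pad_factor' must be >= 1")
  if (!is.finite(distance)) stop("non-finite distance")
  u <- field$samples
  n1 <- nrow(u); n2 <- ncol(u)
  np1 <- pad_factor * n1; np2 <- pad_factor * n2
  o1 <- (np1 - n1) %/% 2L; o2 <- (np2 - n2) %/% 2L
  big <- matrix(0 + 0i, np1, np2)
  big[o1 + seq_len(n1), o2 + seq_len(n2)] <- u
  lam_eff <- field$wavelength / field$medium_index
  fx <- fft_freq(np1, field$pitch)
  fy <- fft_freq(np2, field$pitch)
  FX <- matrix(fx, np1, np2)
  FY <- matrix(fy, np1, np2, byrow = TRUE)
  H <- asm_transfer_function(FX, FY, distance, lam_eff)
  out <- stats::fft(stats::fft(big) * H, inverse = TRUE) / (np1 * np2)
  field$samples <- out[o1 + seq_len(n1), o2 + seq_len(n2), drop = FALSE]
  field
}

#' Dense propagation operator on a fixed grid
#'
#' Builds the linear operator that `propagate()` applies on an `n x n` grid,
#' as a dense `n^2 x n^2` complex matrix acting on column-vectorized fields
#' (R column-major order). Columns are obtained by propagating basis
#' impulses, so the operator agrees with the FFT path to round-off by
#' construction. Used by the training engine, where repeated application to
#' small stacks of fields is faster as a BLAS matrix product.
#'
#' @inheritParams propagate
#' @param n Grid side length.
#' @param wavelength Vacuum wavelength.
#' @param pitch Lateral sampling interval.
#' @param medium_index Refractive index of the medium filling the gap.
#' @return Complex `n^2 x n^2` matrix.
#' @export
propagation_operator <- function(n, pitch, wavelength, distance,
                                 pad_factor = 2L, medium_index = 1) {
  n <- as.integer(n)
  npix <- n * n
  P <- matrix(0 + 0i, npix, npix)
  basis <- matrix(0 + 0i, n, n)
  for (i in seq_len(npix)) {
    basis[i] <- 1 + 0i
    f <- complex_field(basis, wavelength = wavelength, pitch = pitch,
                       medium_index = medium_index)
    P[, i] <- as.vector(propagate(f, distance, pad_factor)$samples)
    basis[i] <- 0 + 0i
  }
  P
}
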