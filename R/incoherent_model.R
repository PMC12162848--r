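# The spatially incoherent intensity forward model: exact impulse-response
# transformation matrices, the Monte-Carlo random-phase ensemble, and the
# o = A i contract connecting them.

#' Realized intensity transformation matrix A'
#'
#' Stacks the vectorized incoherent 3D PSFs of all `N_i` input voxels as the
#' columns of the nonnegative `N_o x N_i` matrix `A'`. Deterministic: no
#' Monte-Carlo averaging is involved, because for a single point emitter the
#' global phase cancels in the squared modulus.
#'
#' @param design A [diffractive_design].
#' @param wavelength Vacuum wavelength.
#' @param bits Surface bit depth (`Inf` = continuous).
#' @param method `"operator"` (dense-operator engine, default) or `"direct"`
#'   (one [point_psf()] per voxel via the FFT path); the two agree to
#'   round-off.
#' @param pad_factor FFT zero-padding factor.
#' @return Nonnegative `N_o x N_i` matrix; rows and columns follow the
#'   plane-major, row-major voxel order of [vectorize_volume()].
#' @export
impulse_matrix <- function(design, wavelength = design$geometry$wavelengths[1L],
                           bits = Inf, method = c("operator", "direct"),
                           pad_factor = 2L) {
  method <- match.arg(method)
  geom <- design$geometry
  if (method == "direct") {
    ci <- geom$input_shape
    cols <- vector("list", prod(ci))
    q <- 1L
    for (n in seq_len(ci[1L])) for (l in seq_len(ci[2L])) for (m in seq_len(ci[3L])) {
      cols[[q]] <- vectorize_volume(point_psf(design, n, l, m, wavelength,
                                              bits, pad_factor))
      q <- q + 1L
    }
    return(do.call(cbind, cols))
  }
  eng <- build_engine(geom, wavelength, pad_factor)
  ph <- design_phases(design, wavelength, bits)
  engine_forward(eng, ph$phases)$Ap
}

#' Incoherent output of an emitter volume via the random-phase ensemble
#'
#' Implements the Monte-Carlo model of spatial incoherence: for each input
#' plane independently, `n_phase` i.i.d. uniform(0, 2*pi) phase maps are
#' drawn, the coherent fields `sqrt(I) * exp(1i * phi)` are propagated
#' through the processor, and the output intensities are averaged; plane
#' contributions are summed (per-plane independence realizes cross-plane
#' incoherence). Multispectral volumes are processed per wavelength channel
#' and summed at the detector, since mutually incoherent spectral channels
#' add in intensity.
#'
#' The master seed expands into one reproducible stream per (wavelength
#' channel, input plane) pair.
#'
#' @param design A [diffractive_design].
#' @param volume An [emitter_volume] (or a nonnegative `(H_i, W_i, C_i)`
#'   array).
#' @param n_phase Number of random-phase realizations (>= 1).
#' @param seed Master seed.
#' @param bits Surface bit depth.
#' @param pad_factor FFT zero-padding factor.
#' @param batch Realizations per matrix product (memory knob).
#' @return Nonnegative `(H_o, W_o, C_o)` array of time-averaged output
#'   intensities.
#' @export
ensemble_output <- function(design, volume, n_phase = 10000L, seed = 1L,
                            bits = Inf, pad_factor = 2L, batch = 500L) {
  n_phase <- as.integer(n_phase)
  if (is.na(n_phase) || n_phase < 1L) stop("'n_phase' must be >= 1")
  vol <- as_emitter_volume(volume)
  geom <- design$geometry
  ci <- geom$input_shape; co <- geom$output_shape
  M <- geom$M
  idx_in <- plane_voxel_indices(M, ci[2L], ci[3L])
  n_vox <- length(idx_in)
  out_vec <- numeric(prod(co))
  wavelengths <- geom$wavelengths
  for (w in seq_along(wavelengths)) {
    I_w <- channel_intensity(vol, w)
    if (all(I_w == 0)) next
    eng <- build_engine(geom, wavelengths[w], pad_factor)
    eng$cached_phases <- design_phases(design, wavelengths[w], bits)$phases
    for (n in seq_len(ci[1L])) {
      amp <- sqrt(vectorize_volume(I_w[, , n, drop = FALSE]))
      if (all(amp == 0)) next
      set.seed(seed + 1000L * (n - 1L) + 100000L * (w - 1L))
      acc <- numeric(prod(co))
      done <- 0L
      while (done < n_phase) {
        b <- min(batch, n_phase - done)
        phi <- matrix(stats::runif(n_vox * b, 0, 2 * pi), n_vox, b)
        U0 <- matrix(0 + 0i, eng$npix, b)
        U0[idx_in, ] <- amp * exp(1i * phi)
        acc <- acc + rowSums(engine_forward_fields(eng, U0, plane = n))
        done <- done + b
      }
      out_vec <- out_vec + acc / n_phase
    }
  }
  unvectorize_volume(out_vec, co)
}

#' Apply an intensity transformation to an emitter volume
#'
#' Matrix-vector product `o = A i` with both vectors in the plane-major,
#' row-major voxel order; the result is reshaped back to the output grid.
#'
#' @param A `N_o x N_i` transformation matrix.
#' @param volume Input volume: an [emitter_volume], a `(H_i, W_i, C_i)`
#'   array, or an already-vectorized nonnegative vector.
#' @param output_shape Integer `c(C_o, H_o, W_o)`; if `NULL` the vectorized
#'   output is returned.
#' @return Output volume array (or vector if `output_shape` is `NULL`).
#' @export
apply_transform <- function(A, volume, output_shape = NULL) {
  i_vec <- if (is.numeric(volume) && is.null(dim(volume))) volume
           else vectorize_volume(intensity_of(volume))
  if (ncol(A) != length(i_vec)) stop("shape mismatch between A and input")
  o <- as.vector(A %*% i_vec)
  if (is.null(output_shape)) o else unvectorize_volume(o, output_shape)
}

#' Optimal global scale between target and realized transformations
#'
#' The closed-form scalar minimizing `||A - sigma * A'||^2`:
#' `sigma = sum(A * A') / sum(A'^2)`. The scaled realized transformation is
#' `Ahat = sigma * A'`; `sigma` absorbs the overall optical throughput.
#'
#' @param A Target transformation matrix.
#' @param Ap Realized (raw) transformation matrix, same shape.
#' @return The scalar `sigma`.
#' @export
optimal_scale <- function(A, Ap) {
  if (!all(dim(A) == dim(Ap))) stop("shape mismatch")
  denom <- sum(Ap^2)
  if (denom == 0) stop("undefined scale: realized transformation is identically zero")
  sum(A * Ap) / denom
}
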