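# Phase-only diffractive surfaces: latent thickness parametrization,
# dispersion-aware phase computation, bit-depth quantization, aperture masking.

#' Material dispersion table
#'
#' Exact lookup table mapping wavelength to refractive index. A single numeric
#' value is treated as a dispersion-free (flat) index valid at all wavelengths.
#'
#' @param wavelength Wavelengths (same unit as the design wavelengths).
#' @param index Refractive indices at those wavelengths.
#' @return An object of class `dispersion`.
#' @examples
#' # diffractive material used for the visible-band multispectral designs
#' dispersion(c(580e-3, 600e-3, 620e-3), c(1.4587, 1.4580, 1.4574))
#' @export
dispersion <- function(wavelength, index) {
  stopifnot(length(wavelength) == length(index), all(index > 0))
  structure(list(wavelength = as.numeric(wavelength), index = as.numeric(index)),
            class = "dispersion")
}

#' Refractive index at a wavelength
#'
#' @param material A [dispersion] table or a single numeric (flat index).
#' @param wavelength Query wavelength; must match a table entry exactly
#'   (within round-off) for tabulated materials.
#' @return Refractive index (scalar).
#' @export
refractive_index <- function(material, wavelength) {
  if (is.numeric(material) && length(material) == 1L) return(material)
  stopifnot(inherits(material, "dispersion"))
  i <- which(abs(material$wavelength - wavelength) <=
               1e-9 * max(wavelength, material$wavelength))
  if (length(i) == 0L)
    stop(sprintf("no dispersion entry for wavelength %g", wavelength))
  material$index[i[1L]]
}

#' Thickness from the unconstrained latent variable
#'
#' `t = (t_max / 2) * (sin(latent) + 1)`, elementwise, which confines the
#' physical thickness to `[0, t_max]` while leaving the optimizer free to move
#' in an unconstrained parameter space.
#'
#' @param latent Numeric array of latent values.
#' @param t_max Maximum thickness (> 0).
#' @return Thickness array in `[0, t_max]`, same shape as `latent`.
#' @examples
#' thickness_from_latent(pi / 2, t_max = 2)  # == t_max
#' @export
thickness_from_latent <- function(latent, t_max) {
  stopifnot(t_max > 0)
  (t_max / 2) * (sin(latent) + 1)
}

#' Phase delay of a surface from its thickness
#'
#' `phi = (2 * pi / wavelength) * (eta - 1) * t`, elementwise and unwrapped,
#' where `eta` is the refractive index of the diffractive material at the
#' wavelength. A thickness of `wavelength / (eta - 1)` gives a full `2*pi`
#' modulation depth.
#'
#' @param thickness Thickness array.
#' @param wavelength Vacuum wavelength.
#' @param eta Refractive index of the surface material at `wavelength` (> 1).
#' @return Phase array in radians (not wrapped).
#' @export
phase_from_thickness <- function(thickness, wavelength, eta) {
  if (eta <= 1) stop("'eta' must be > 1 for a phase-delaying material")
  (2 * pi / wavelength) * (eta - 1) * thickness
}

#' Quantize a phase map to a given bit depth
#'
#' With a bounded bit depth `b` the phase is wrapped to `[0, 2*pi)` and
#' snapped to the nearest of the `2^b` uniformly spaced levels
#' `{0, 2*pi/2^b, ...}`; values nearer to `2*pi` than to the top level wrap
#' around to level 0. `b = Inf` means continuous phase modulation and returns
#' the input unchanged.
#'
#' @param phi Phase array (radians).
#' @param bits Positive integer bit depth, or `Inf` for continuous phase.
#' @return Quantized phase array; the quantization error never exceeds
#'   `pi / 2^b` after wrapping.
#' @examples
#' quantize_phase(0.6 * pi, 1)  # snaps to pi
#' @export
quantize_phase <- function(phi, bits) {
  if (is.infinite(bits)) return(phi)
  if (!is.finite(bits) || bits < 1) stop("'bits' must be >= 1 or Inf")
  levels <- 2^bits
  step <- 2 * pi / levels
  wrapped <- phi %% (2 * pi)
  (round(wrapped / step) %% levels) * step
}

#' Quantize a thickness map to a given bit depth
#'
#' Snaps thickness to the `2^b` levels `{0, t_max/2^b, ...}` with wrap-around
#' at `t_max` (equivalent to phase quantization at the wavelength whose
#' modulation depth is exactly `2*pi`). Used for multiwavelength designs so
#' that a single physical thickness profile is quantized consistently across
#' all wavelengths.
#'
#' @param thickness Thickness array in `[0, t_max]`.
#' @param t_max Maximum thickness.
#' @param bits Positive integer bit depth, or `Inf` for continuous values.
#' @return Quantized thickness array.
#' @export
quantize_thickness <- function(thickness, t_max, bits) {
  if (is.infinite(bits)) return(thickness)
  if (!is.finite(bits) || bits < 1) stop("'bits' must be >= 1 or Inf")
  levels <- 2^bits
  step <- t_max / levels
  (round((thickness %% t_max) / step) %% levels) * step
}

#' Training/evaluation bit-depth policy
#'
#' @param b_train Bit depth applied during optimization (`Inf` = continuous).
#' @param b_test Bit depth applied at evaluation time.
#' @return An object of class `bit_depth_policy`.
#' @export
bit_depth_policy <- function(b_train = Inf, b_test = b_train) {
  for (b in c(b_train, b_test))
    if (!is.infinite(b) && (!is.finite(b) || b < 1 || b != round(b)))
      stop("bit depths must be positive integers or Inf")
  structure(list(b_train = b_train, b_test = b_test), class = "bit_depth_policy")
}

#' Phase-only diffractive surface
#'
#' A surface is defined by a square grid of latent values (one per diffractive
#' feature), the maximum thickness `t_max`, the feature pitch, and the material
#' dispersion. The physical thickness is derived by [thickness_from_latent()]
#' and the per-wavelength phase by [phase_from_thickness()].
#'
#' @param latent Square numeric matrix of latent values.
#' @param t_max Maximum thickness.
#' @param pitch Feature pitch (equal to the field sampling interval).
#' @param material A [dispersion] table or flat numeric index for the
#'   diffractive material.
#' @return An object of class `diffractive_surface`.
#' @export
diffractive_surface <- function(latent, t_max, pitch, material) {
  if (!is.matrix(latent) || nrow(latent) != ncol(latent))
    stop("'latent' must be a square matrix")
  stopifnot(t_max > 0, pitch > 0)
  structure(list(latent = latent, t_max = t_max, pitch = pitch,
                 material = material),
            class = "diffractive_surface")
}

#' Thickness map of a surface
#'
#' @param surface A [diffractive_surface].
#' @param bits Optional thickness bit depth (`Inf` = continuous).
#' @return Thickness matrix in `[0, t_max]`.
#' @export
surface_thickness <- function(surface, bits = Inf) {
  t_s <- thickness_from_latent(surface$latent, surface$t_max)
  quantize_thickness(t_s, surface$t_max, bits)
}

#' Phase map of a surface at a wavelength
#'
#' For single-wavelength use the (unwrapped) phase is quantized directly;
#' multiwavelength designs should quantize thickness instead (see
#' [surface_thickness()]) so one physical device is consistent across
#' wavelengths.
#'
#' @param surface A [diffractive_surface].
#' @param wavelength Vacuum wavelength.
#' @param bits Phase bit depth (`Inf` = continuous).
#' @param quantize_domain `"phase"` (monochrome default) or `"thickness"`.
#' @return Phase matrix in radians.
#' @export
surface_phase <- function(surface, wavelength, bits = Inf,
                          quantize_domain = c("phase", "thickness")) {
  quantize_domain <- match.arg(quantize_domain)
  eta <- refractive_index(surface$material, wavelength)
  if (quantize_domain == "thickness") {
    t_s <- surface_thickness(surface, bits)
    phase_from_thickness(t_s, wavelength, eta)
  } else {
    phi <- phase_from_thickness(surface_thickness(surface), wavelength, eta)
    quantize_phase(phi, bits)
  }
}

#' Modulate a field by a diffractive surface
#'
#' Within the surface aperture (the central `M x M` feature block) the field is
#' multiplied by `exp(1i * phi)`; the amplitude is unchanged (phase-only).
#' Outside the aperture the field is blocked (set to 0) by default, modeling an
#' opaque mount; `aperture = "open"` leaves the surround untouched instead.
#'
#' @param field A [complex_field] whose pitch equals the surface pitch and
#'   whose grid is at least as large as the surface grid.
#' @param surface A [diffractive_surface].
#' @param wavelength Vacuum wavelength used to evaluate the phase.
#' @param bits Bit depth for quantization (`Inf` = continuous).
#' @param aperture `"block"` (default) or `"open"`.
#' @param quantize_domain Passed to [surface_phase()].
#' @return The modulated [complex_field].
#' @export
modulate <- function(field, surface, wavelength = field$wavelength, bits = Inf,
                     aperture = c("block", "open"),
                     quantize_domain = c("phase", "thickness")) {
  aperture <- match.arg(aperture)
  quantize_domain <- match.arg(quantize_domain)
  stopifnot(inherits(field, "complex_field"), inherits(surface, "diffractive_surface"))
  if (abs(field$pitch - surface$pitch) > 1e-12 * surface$pitch)
    stop("field pitch does not match the surface feature pitch")
  m <- nrow(surface$latent)
  n1 <- nrow(field$samples); n2 <- ncol(field$samples)
  if (n1 < m || n2 < m) stop("field grid smaller than the surface grid")
  phi <- surface_phase(surface, wavelength, bits, quantize_domain)
  o1 <- (n1 - m) %/% 2L; o2 <- (n2 - m) %/% 2L
  rows <- o1 + seq_len(m); cols <- o2 + seq_len(m)
  out <- field$samples
  out[rows, cols] <- out[rows, cols] * exp(1i * phi)
  if (aperture == "block") {
    mask <- matrix(FALSE, n1, n2)
    mask[rows, cols] <- TRUE
    out[!mask] <- 0 + 0i
  }
  field$samples <- out
  field
}
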