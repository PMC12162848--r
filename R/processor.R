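# Geometry of the cascaded processor and coherent end-to-end propagation.

#' Default layer-to-layer separation
#'
#' `d = (W * pitch / wavelength) * sqrt(1 - (wavelength / (2 * pitch))^2)`,
#' which keeps the diffractive connectivity between successive layers constant
#' as the layer width `W` changes.
#'
#' @param width Layer width `W`.
#' @param pitch Feature pitch.
#' @param wavelength Vacuum wavelength.
#' @return Axial separation between successive surfaces.
#' @export
layer_separation <- function(width, pitch, wavelength) {
  (width * pitch / wavelength) * sqrt(1 - (wavelength / (2 * pitch))^2)
}

#' Numerical aperture implied by the geometry
#'
#' `NA = medium_index * sin(atan((W / 2) / d))` where `d` is the distance of
#' the farthest input (or output) plane from the nearest surface.
#'
#' @param width Layer width `W`.
#' @param d Distance of the farthest plane from the first/last surface.
#' @param medium_index Refractive index of the immersing medium.
#' @return Numerical aperture.
#' @examples
#' numerical_aperture(57, 21)  # approximately 0.81
#' @export
numerical_aperture <- function(width, d, medium_index = 1) {
  medium_index * sin(atan((width / 2) / d))
}

#' Axial diffraction limit
#'
#' The axial resolution limit `2 * wavelength / NA^2` of a system with
#' numerical aperture `na`. Plane-to-plane spacings below this limit cannot be
#' resolved and lead to monotonically increasing transformation error.
#'
#' @param na Numerical aperture.
#' @param wavelength Vacuum wavelength (default 1, i.e. result in wavelength
#'   units).
#' @return Axial limit in the same unit as `wavelength`.
#' @examples
#' axial_limit(0.81)  # approximately 3.05 wavelengths
#' @export
axial_limit <- function(na, wavelength = 1) 2 * wavelength / na^2

# Reference numerical aperture used for the default d_i = d_o choice; matches
# the W = 57 lambda, d_i = 21 lambda configuration (NA ~ 0.81).
.reference_na <- 0.81

#' Processor geometry
#'
#' Full axial/lateral layout of a cascaded diffractive processor: `K` surfaces
#' of `M x M` features (total `N = K * M^2`), layer width `W = M * pitch`,
#' inter-surface separation `d`, the distances `d_i` / `d_o` of the farthest
#' input/output planes from the first/last surface, the intra-volume plane
#' spacing `d_pp`, and the voxel grids of the input and output volumes.
#'
#' Axial convention: input plane 1 is the farthest from the processor (at
#' `d_i` before surface 1), successive input planes sit `d_pp` closer; output
#' plane `C_o` is the farthest (at `d_o` after surface K), plane 1 the
#' nearest. Defaults follow the diffraction-limited discretization
#' `pitch = 0.53 * wavelength`, `d_pp = 2.67 * wavelength`, the
#' connectivity-preserving [layer_separation()], and a `d_i = d_o` chosen so
#' the input/output numerical aperture equals the reference value 0.81.
#'
#' @param K Number of diffractive surfaces (>= 1).
#' @param M Features per side of each surface; also the simulation grid side.
#' @param wavelengths Vacuum wavelength(s); lengths default to units of the
#'   median wavelength.
#' @param input_shape Integer `c(C_i, H_i, W_i)`: planes, rows, columns of the
#'   input voxel grid.
#' @param output_shape Integer `c(C_o, H_o, W_o)` for the output grid;
#'   defaults to `input_shape`.
#' @param pitch Lateral sampling interval and feature pitch.
#' @param d Layer-to-layer separation; default [layer_separation()].
#' @param d_i Distance of the farthest input plane from surface 1; default
#'   sets the input NA to 0.81 (and is never smaller than the span
#'   `(C_i - 1) * d_pp` of the input volume).
#' @param d_o Same for the output side; defaults to `d_i`.
#' @param d_pp Plane-to-plane distance inside the volumes.
#' @param medium Optional [dispersion] table (or flat numeric index) of the
#'   medium immersing the emitters; `NULL` means free space.
#' @param medium_extent `"input"`: the medium fills the input volume up to the
#'   first surface; `"none"`: ignore the medium.
#' @param aperture `"block"` (opaque surround at every surface, default) or
#'   `"open"`.
#' @return An object of class `processor_geometry`.
#' @export
processor_geometry <- function(K, M, wavelengths = 1,
                               input_shape = c(2L, 3L, 3L),
                               output_shape = input_shape,
                               pitch = NULL, d = NULL, d_i = NULL, d_o = NULL,
                               d_pp = NULL, medium = NULL,
                               medium_extent = c("input", "none"),
                               aperture = c("block", "open")) {
  medium_extent <- match.arg(medium_extent)
  aperture <- match.arg(aperture)
  K <- as.integer(K); M <- as.integer(M)
  stopifnot(K >= 1L, M >= 1L, length(input_shape) == 3L, length(output_shape) == 3L)
  input_shape <- as.integer(input_shape); output_shape <- as.integer(output_shape)
  if (any(input_shape < 1L) || any(output_shape < 1L)) stop("invalid volume shape")
  if (max(input_shape[2:3]) > M || max(output_shape[2:3]) > M)
    stop("volume lateral extent exceeds the layer grid")
  lambda_ref <- stats::median(wavelengths)
  if (is.null(pitch)) pitch <- 0.53 * lambda_ref
  if (is.null(d_pp)) d_pp <- 2.67 * lambda_ref
  W <- M * pitch
  if (is.null(d)) d <- layer_separation(W, pitch, lambda_ref)
  if (is.null(d_i)) {
    d_i <- (W / 2) / tan(asin(.reference_na))
    d_i <- max(d_i, (input_shape[1L] - 1L) * d_pp)
  }
  if (is.null(d_o)) {
    d_o <- (W / 2) / tan(asin(.reference_na))
    d_o <- max(d_o, (output_shape[1L] - 1L) * d_pp)
  }
  stopifnot(pitch > 0, d_pp > 0, d > 0, d_i > 0, d_o > 0)
  if (d_i < (input_shape[1L] - 1L) * d_pp)
    stop("d_i smaller than the axial span of the input volume")
  if (d_o < (output_shape[1L] - 1L) * d_pp)
    stop("d_o smaller than the axial span of the output volume")
  structure(list(K = K, M = M, N = K * M * M, wavelengths = wavelengths,
                 pitch = pitch, width = W, d = d, d_i = d_i, d_o = d_o,
                 d_pp = d_pp, input_shape = input_shape,
                 output_shape = output_shape, medium = medium,
                 medium_extent = medium_extent, aperture = aperture),
            class = "processor_geometry")
}

#' @export
print.processor_geometry <- function(x, ...) {
  cat(sprintf(paste0("<processor_geometry K=%d, M=%d (N=%d), W=%.3g, d=%.3g, ",
                     "d_i=%.3g, d_o=%.3g, d_pp=%.3g>\n"),
              x$K, x$M, x$N, x$width, x$d, x$d_i, x$d_o, x$d_pp))
  cat(sprintf("  input %s, output %s, wavelengths %s\n",
              paste(x$input_shape, collapse = "x"),
              paste(x$output_shape, collapse = "x"),
              paste(signif(x$wavelengths, 4), collapse = ", ")))
  invisible(x)
}

# Medium refractive index seen by the input segment at a wavelength.
medium_index_at <- function(geometry, wavelength) {
  if (is.null(geometry$medium) || geometry$medium_extent == "none") return(1)
  refractive_index(geometry$medium, wavelength)
}

# --- vectorization convention -------------------------------------------------
# Voxels are ordered plane-major, then row-major within a plane:
# q = (plane - 1) * H * W + (row - 1) * W + col  (1-based).

#' Vectorize a voxel volume
#'
#' Flattens a `(H, W, C)` array (rows, columns, planes) into the package-wide
#' voxel order: plane-major, then row-major within each plane. This fixes the
#' row/column order of every transformation matrix.
#'
#' @param volume 3D array with dimensions `(H, W, C)`.
#' @return Numeric vector of length `H * W * C`.
#' @export
vectorize_volume <- function(volume) {
  stopifnot(length(dim(volume)) == 3L)
  as.vector(aperm(volume, c(2L, 1L, 3L)))
}

#' Reshape a vector back into a voxel volume
#'
#' Inverse of [vectorize_volume()].
#'
#' @param x Vector of voxel values in plane-major, row-major order.
#' @param shape Integer `c(C, H, W)`.
#' @return 3D array with dimensions `(H, W, C)`.
#' @export
unvectorize_volume <- function(x, shape) {
  stopifnot(length(x) == prod(shape))
  aperm(array(x, dim = c(shape[3L], shape[2L], shape[1L])), c(2L, 1L, 3L))
}

# Linear indices (into the column-major M x M grid) of the centered H x W
# voxel block, in row-major voxel order (column index fastest).
plane_voxel_indices <- function(M, H, W) {
  r0 <- (M - H) %/% 2L; c0 <- (M - W) %/% 2L
  idx <- integer(H * W)
  k <- 1L
  for (l in seq_len(H)) for (m in seq_len(W)) {
    idx[k] <- (c0 + m - 1L) * M + (r0 + l)
    k <- k + 1L
  }
  idx
}

# Axial distance from input plane n' to surface 1 / surface K to output plane n.
input_plane_distance <- function(geometry, plane) {
  stopifnot(plane >= 1L, plane <= geometry$input_shape[1L])
  geometry$d_i - (plane - 1L) * geometry$d_pp
}
output_plane_distance <- function(geometry, plane) {
  C_o <- geometry$output_shape[1L]
  stopifnot(plane >= 1L, plane <= C_o)
  geometry$d_o - (C_o - plane) * geometry$d_pp
}

# --- design -------------------------------------------------------------------

#' Default maximum thickness for a design
#'
#' `max_i wavelength_i / (eta(wavelength_i) - 1)`: the thickness giving a full
#' `2 * pi` phase modulation depth (at the most demanding wavelength for
#' multiwavelength designs).
#'
#' @param wavelengths Design wavelength(s).
#' @param material Surface material ([dispersion] or flat index).
#' @return Maximum thickness.
#' @export
default_t_max <- function(wavelengths, material) {
  max(vapply(wavelengths,
             function(l) l / (refractive_index(material, l) - 1),
             numeric(1)))
}

#' Diffractive processor design
#'
#' Bundles a [processor_geometry] with `K` phase-only surfaces sharing one
#' material and maximum thickness. Latents are initialized i.i.d.
#' uniform(-pi, pi) (thickness near mid-range on average, away from the
#' saturation regions of the sine reparametrization) unless given explicitly.
#'
#' @param geometry A [processor_geometry].
#' @param material Surface material ([dispersion] table or flat numeric
#'   index); default 1.6518, the reference diffractive material index.
#' @param seed Integer seed for latent initialization.
#' @param latents Optional list of `K` `M x M` latent matrices.
#' @param t_max Maximum thickness; default [default_t_max()].
#' @return An object of class `diffractive_design`.
#' @export
diffractive_design <- function(geometry, material = 1.6518, seed = 1L,
                               latents = NULL, t_max = NULL) {
  stopifnot(inherits(geometry, "processor_geometry"))
  if (is.null(t_max)) t_max <- default_t_max(geometry$wavelengths, material)
  M <- geometry$M
  if (is.null(latents)) {
    set.seed(seed)
    latents <- lapply(seq_len(geometry$K),
                      function(k) matrix(stats::runif(M^2, -pi, pi), M, M))
  }
  stopifnot(length(latents) == geometry$K,
            all(vapply(latents, function(l) all(dim(l) == c(M, M)), logical(1))))
  structure(list(geometry = geometry, material = material, t_max = t_max,
                 latents = latents, seed = seed),
            class = "diffractive_design")
}

#' Surfaces of a design
#'
#' @param design A [diffractive_design].
#' @return List of `K` [diffractive_surface] objects.
#' @export
design_surfaces <- function(design) {
  lapply(design$latents, function(l)
    diffractive_surface(l, t_max = design$t_max, pitch = design$geometry$pitch,
                        material = design$material))
}

# Quantization domain: monochrome designs quantize phase, multiwavelength
# designs quantize the shared physical thickness.
quantize_domain_of <- function(design) {
  if (length(design$geometry$wavelengths) > 1L) "thickness" else "phase"
}

#' Coherent field propagation through the whole processor
#'
#' Propagates a complex field from input plane `input_plane` through the
#' immersion medium segment (if configured), each of the `K` surfaces
#' (modulation followed by the free-space gap `d`), and on to output plane
#' `output_plane`. This is the coherent building block of the incoherent
#' intensity model.
#'
#' @param design A [diffractive_design].
#' @param samples Complex matrix of field samples at the input plane (grid at
#'   least `M x M`, pitch equal to the geometry pitch).
#' @param input_plane Input plane index in `1..C_i`.
#' @param output_plane Output plane index in `1..C_o`.
#' @param wavelength Vacuum wavelength (default: first design wavelength).
#' @param bits Bit depth applied to the surfaces (`Inf` = continuous).
#' @param pad_factor FFT zero-padding factor.
#' @return A [complex_field] at the requested output plane.
#' @export
coherent_cascade <- function(design, samples, input_plane = 1L,
                             output_plane = 1L,
                             wavelength = design$geometry$wavelengths[1L],
                             bits = Inf, pad_factor = 2L) {
  geom <- design$geometry
  if (input_plane < 1L || input_plane > geom$input_shape[1L])
    stop("input plane index out of range")
  if (output_plane < 1L || output_plane > geom$output_shape[1L])
    stop("output plane index out of range")
  surfaces <- design_surfaces(design)
  qd <- quantize_domain_of(design)
  field <- complex_field(samples, wavelength = wavelength, pitch = geom$pitch,
                         medium_index = medium_index_at(geom, wavelength))
  field <- propagate(field, input_plane_distance(geom, input_plane), pad_factor)
  field$medium_index <- 1
  for (k in seq_len(geom$K)) {
    field <- modulate(field, surfaces[[k]], wavelength, bits,
                      aperture = geom$aperture, quantize_domain = qd)
    gap <- if (k < geom$K) geom$d else output_plane_distance(geom, output_plane)
    field <- propagate(field, gap, pad_factor)
  }
  field
}

#' Incoherent 3D point spread function of one input voxel
#'
#' Places a unit-amplitude impulse at input voxel `(plane, row, col)`, runs the
#' coherent cascade to every output plane, and samples the squared modulus on
#' the output voxel grid.
#'
#' @param design A [diffractive_design].
#' @param plane,row,col Voxel index within the input grid `(C_i, H_i, W_i)`.
#' @param wavelength Vacuum wavelength.
#' @param bits Surface bit depth.
#' @param pad_factor FFT zero-padding factor.
#' @return Nonnegative 3D array `(H_o, W_o, C_o)` of output intensities.
#' @export
point_psf <- function(design, plane, row, col,
                      wavelength = design$geometry$wavelengths[1L],
                      bits = Inf, pad_factor = 2L) {
  geom <- design$geometry
  ci <- geom$input_shape
  if (plane < 1L || plane > ci[1L] || row < 1L || row > ci[2L] ||
      col < 1L || col > ci[3L])
    stop("invalid input voxel index")
  M <- geom$M
  r0 <- (M - ci[2L]) %/% 2L; c0 <- (M - ci[3L]) %/% 2L
  u0 <- matrix(0 + 0i, M, M)
  u0[r0 + row, c0 + col] <- 1 + 0i
  surfaces <- design_surfaces(design)
  qd <- quantize_domain_of(design)
  field <- complex_field(u0, wavelength = wavelength, pitch = geom$pitch,
                         medium_index = medium_index_at(geom, wavelength))
  field <- propagate(field, input_plane_distance(geom, plane), pad_factor)
  field$medium_index <- 1
  for (k in seq_len(geom$K)) {
    field <- modulate(field, surfaces[[k]], wavelength, bits,
                      aperture = geom$aperture, quantize_domain = qd)
    if (k < geom$K) field <- propagate(field, geom$d, pad_factor)
  }
  co <- geom$output_shape
  C_o <- co[1L]
  out <- array(0, dim = c(co[2L], co[3L], C_o))
  ro <- (M - co[2L]) %/% 2L; cc <- (M - co[3L]) %/% 2L
  field <- propagate(field, output_plane_distance(geom, 1L), pad_factor)
  for (n in seq_len(C_o)) {
    if (n > 1L) field <- propagate(field, geom$d_pp, pad_factor)
    out[, , n] <- Mod(field$samples[ro + seq_len(co[2L]), cc + seq_len(co[3L]),
                                    drop = FALSE])^2
  }
  out
}
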