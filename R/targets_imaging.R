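# Target transformations (random-uniform and Kronecker imaging maps with
# superpixel layouts) and demultiplexing of raw detector frames.

#' Superpixel layout for snapshot (multispectral) 3D imaging
#'
#' Groups the pixels of a single output detector plane into `H_i x W_i`
#' superpixels, one per lateral input pixel. Each superpixel is an `s x s`
#' block with `s = ceiling(sqrt(C_i * n_wavelengths))`; the constituent
#' offsets pack the (input plane, wavelength) pairs row-major into the block,
#' so constituent assignments are disjoint and deterministic. Block cells
#' beyond `C_i * n_wavelengths` stay unassigned (target 0 for every input).
#'
#' @param input_shape Integer `c(C_i, H_i, W_i)` of the input volume.
#' @param n_wavelengths Number of emission wavelength channels (default 1).
#' @return An object of class `superpixel_layout` with the output grid shape
#'   `c(1, H_i * s, W_i * s)`.
#' @examples
#' superpixel_layout(c(4L, 6L, 6L))   # 2x2 superpixels, 12x12 output plane
#' @export
superpixel_layout <- function(input_shape, n_wavelengths = 1L) {
  stopifnot(length(input_shape) == 3L, n_wavelengths >= 1L)
  input_shape <- as.integer(input_shape)
  C_i <- input_shape[1L]; H <- input_shape[2L]; W <- input_shape[3L]
  L <- as.integer(n_wavelengths)
  s <- as.integer(ceiling(sqrt(C_i * L)))
  structure(list(input_shape = input_shape, n_wavelengths = L, block = s,
                 output_shape = c(1L, H * s, W * s)),
            class = "superpixel_layout")
}

# Constituent offset (0-based row/col within the s x s block) of a
# (plane, wavelength) pair.
layout_offset <- function(layout, plane, wavelength_channel = 1L) {
  j <- (plane - 1L) * layout$n_wavelengths + (wavelength_channel - 1L)
  c(row = j %/% layout$block, col = j %% layout$block)
}

# Output pixel (row, col) on the detector plane for input voxel
# (plane, l, m) and wavelength channel w.
layout_pixel <- function(layout, plane, l, m, w = 1L) {
  off <- layout_offset(layout, plane, w)
  c(row = (l - 1L) * layout$block + off[["row"]] + 1L,
    col = (m - 1L) * layout$block + off[["col"]] + 1L)
}

#' Random-uniform target transformation
#'
#' Entries i.i.d. uniform(0, 1): an arbitrary set of `n_in` nonnegative
#' spatially varying 3D PSFs.
#'
#' @param n_out,n_in Matrix dimensions (`N_o x N_i`).
#' @param seed Integer seed.
#' @return `n_out x n_in` matrix with entries in `[0, 1]`.
#' @export
random_uniform_target <- function(n_out, n_in, seed = 1L) {
  stopifnot(n_out >= 1L, n_in >= 1L)
  set.seed(seed)
  matrix(stats::runif(n_out * n_in), n_out, n_in)
}

#' Snapshot 3D imaging target (single wavelength)
#'
#' Kronecker-delta target: `A[p, q] = 1` iff output pixel `p` is the
#' layout-assigned pixel of input voxel `q`, else 0. Exactly one 1 per
#' column, at most one per row; when the superpixel block is exactly filled
#' (`s^2 == C_i`) the matrix is a permutation.
#'
#' @param layout A [superpixel_layout] with `n_wavelengths == 1`.
#' @return `N_o x N_i` 0/1 matrix in the package voxel order.
#' @export
snapshot3d_target <- function(layout) {
  stopifnot(inherits(layout, "superpixel_layout"))
  if (layout$n_wavelengths != 1L)
    stop("single-wavelength target requires a single-channel layout")
  multispectral_target(layout)[[1L]]
}

#' Multispectral snapshot 3D imaging targets
#'
#' One target matrix per wavelength channel. `A_w` maps each voxel (at its
#' plane) to the pixel assigned to its (plane, wavelength `w`) pair; every
#' pixel assigned to another wavelength is an explicit all-zero row, so the
#' training loss penalizes spectral leakage rather than assuming it away.
#'
#' @param layout A [superpixel_layout].
#' @return List of `n_wavelengths` matrices of shape `N_o x N_i`.
#' @export
multispectral_target <- function(layout) {
  stopifnot(inherits(layout, "superpixel_layout"))
  ci <- layout$input_shape
  N_i <- prod(ci)
  os <- layout$output_shape
  N_o <- prod(os)
  W_o <- os[3L]
  lapply(seq_len(layout$n_wavelengths), function(w) {
    A <- matrix(0, N_o, N_i)
    q <- 1L
    for (n in seq_len(ci[1L])) for (l in seq_len(ci[2L])) for (m in seq_len(ci[3L])) {
      px <- layout_pixel(layout, n, l, m, w)
      p <- (px[["row"]] - 1L) * W_o + px[["col"]]
      A[p, q] <- 1
      q <- q + 1L
    }
    A
  })
}

#' Assemble per-plane (per-wavelength) images into a raw detector frame
#'
#' Inverse of [demultiplex()]: writes each image pixel to its layout-assigned
#' constituent within the superpixel; unassigned constituents are 0.
#'
#' @param images Array `(H_i, W_i, C_i)` or `(H_i, W_i, C_i, n_wavelengths)`.
#' @param layout A [superpixel_layout].
#' @return Detector frame matrix `(H_i * s) x (W_i * s)`.
#' @export
multiplex <- function(images, layout) {
  stopifnot(inherits(layout, "superpixel_layout"))
  ci <- layout$input_shape; L <- layout$n_wavelengths
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  if (!all(dim(images) == c(ci[2L], ci[3L], ci[1L], L)))
    stop("image stack shape does not match the layout")
  frame <- matrix(0, layout$output_shape[2L], layout$output_shape[3L])
  for (w in seq_len(L)) for (n in seq_len(ci[1L]))
    for (l in seq_len(ci[2L])) for (m in seq_len(ci[3L])) {
      px <- layout_pixel(layout, n, l, m, w)
      frame[px[["row"]], px[["col"]]] <- images[l, m, n, w]
    }
  frame
}

#' Demultiplex a raw detector frame into per-plane, per-wavelength images
#'
#' Pure index rearrangement (no arithmetic): reads each layout-assigned
#' constituent pixel back into the image of its (plane, wavelength) pair.
#' Exact inverse of [multiplex()].
#'
#' @param frame Detector frame matrix `(H_i * s) x (W_i * s)`.
#' @param layout A [superpixel_layout].
#' @return Array `(H_i, W_i, C_i, n_wavelengths)` (last dimension dropped for
#'   single-wavelength layouts).
#' @export
demultiplex <- function(frame, layout) {
  stopifnot(inherits(layout, "superpixel_layout"))
  ci <- layout$input_shape; L <- layout$n_wavelengths
  if (!all(dim(frame) == layout$output_shape[2:3]))
    stop("frame shape does not match the layout")
  images <- array(0, dim = c(ci[2L], ci[3L], ci[1L], L))
  for (w in seq_len(L)) for (n in seq_len(ci[1L]))
    for (l in seq_len(ci[2L])) for (m in seq_len(ci[3L])) {
      px <- layout_pixel(layout, n, l, m, w)
      images[l, m, n, w] <- frame[px[["row"]], px[["col"]]]
    }
  if (L == 1L) dim(images) <- dim(images)[1:3]
  images
}

#' Spectral cross-talk of a realized multispectral transformation
#'
#' Fraction of total output energy that lands on pixels assigned to other
#' wavelength channels, averaged over input voxels. For a converged design
#' this leakage is small.
#'
#' @param Ap_list List of realized per-wavelength matrices `A'_w`.
#' @param layout A [superpixel_layout].
#' @return Scalar in `[0, 1]`.
#' @export
spectral_crosstalk <- function(Ap_list, layout) {
  stopifnot(inherits(layout, "superpixel_layout"))
  L <- layout$n_wavelengths
  if (L < 2L) stop("cross-talk needs at least two wavelength channels")
  stopifnot(length(Ap_list) == L)
  A_list <- multispectral_target(layout)
  own <- 0; other <- 0
  for (w in seq_len(L)) {
    assigned_w <- rowSums(A_list[[w]]) > 0
    other_w <- rowSums(Reduce(`+`, A_list[-w])) > 0
    own <- own + sum(Ap_list[[w]][assigned_w, ])
    other <- other + sum(Ap_list[[w]][other_w, ])
  }
  other / (own + other)
}
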