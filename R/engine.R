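# Dense-operator cascade engine used by the training module.
#
# For the small grids used in inverse design it is faster to precompute each
# free-space propagation step as a dense complex operator (columns = basis
# impulse responses of `propagate()`, so the operator path agrees with the FFT
# path to round-off) and to push all N_i impulse fields through the cascade as
# one complex matrix product per step. The adjoint of a propagation step is
# its conjugate transpose, which makes reverse-mode gradients exact.

# Build the per-wavelength engine for a geometry: propagation operators (and
# adjoints), voxel index maps, and the per-surface phase scale factors.
build_engine <- function(geometry, wavelength, pad_factor = 2L) {
  M <- geometry$M
  npix <- M * M
  C_i <- geometry$input_shape[1L]; C_o <- geometry$output_shape[1L]
  eta_m <- medium_index_at(geometry, wavelength)
  pop <- function(dist, med = 1) {
    propagation_operator(M, geometry$pitch, wavelength, dist,
                         pad_factor = pad_factor, medium_index = med)
  }
  P_in <- lapply(seq_len(C_i), function(n)
    pop(input_plane_distance(geometry, n), med = eta_m))
  P_gap <- if (geometry$K > 1L) pop(geometry$d) else NULL
  P_out1 <- pop(output_plane_distance(geometry, 1L))
  P_pp <- if (C_o > 1L) pop(geometry$d_pp) else NULL
  list(
    npix = npix, C_i = C_i, C_o = C_o, K = geometry$K,
    wavelength = wavelength,
    P_in = P_in, P_gap = P_gap, P_out1 = P_out1, P_pp = P_pp,
    P_gapH = if (!is.null(P_gap)) Conj(t(P_gap)) else NULL,
    P_out1H = Conj(t(P_out1)),
    P_ppH = if (!is.null(P_pp)) Conj(t(P_pp)) else NULL,
    idx_in = plane_voxel_indices(M, geometry$input_shape[2L],
                                 geometry$input_shape[3L]),
    idx_out = plane_voxel_indices(M, geometry$output_shape[2L],
                                  geometry$output_shape[3L])
  )
}

# Forward cascade of all N_i impulse fields. `phases` is a list of K numeric
# vectors (length npix) of surface phase delays at this wavelength. Returns
# the realized transformation matrix A' (N_o x N_i, plane-major rows/columns)
# plus the intermediate fields needed by the backward pass.
engine_forward <- function(eng, phases) {
  U <- do.call(cbind, lapply(seq_len(eng$C_i),
                             function(n) eng$P_in[[n]][, eng$idx_in, drop = FALSE]))
  V <- vector("list", eng$K)
  for (k in seq_len(eng$K)) {
    V[[k]] <- U * exp(1i * phases[[k]])
    U <- if (k < eng$K) eng$P_gap %*% V[[k]] else eng$P_out1 %*% V[[k]]
  }
  W <- vector("list", eng$C_o)
  W[[1L]] <- U
  if (eng$C_o > 1L)
    for (n in 2L:eng$C_o) W[[n]] <- eng$P_pp %*% W[[n - 1L]]
  n_vox_out <- length(eng$idx_out)
  Ap <- do.call(rbind, lapply(seq_len(eng$C_o), function(n)
    Mod(W[[n]][eng$idx_out, , drop = FALSE])^2))
  list(Ap = Ap, V = V, W = W, phases = phases, n_vox_out = n_vox_out)
}

# Forward pass for arbitrary input fields (columns of U0, one per plane
# group): used by the Monte-Carlo ensemble model. `plane` selects the input
# propagator. Returns output intensities at the output voxels (N_o x ncol).
engine_forward_fields <- function(eng, U0, plane) {
  U <- eng$P_in[[plane]] %*% U0
  for (k in seq_len(eng$K)) {
    U <- U * exp(1i * eng$cached_phases[[k]])
    U <- if (k < eng$K) eng$P_gap %*% U else eng$P_out1 %*% U
  }
  out <- vector("list", eng$C_o)
  out[[1L]] <- Mod(U[eng$idx_out, , drop = FALSE])^2
  if (eng$C_o > 1L)
    for (n in 2L:eng$C_o) {
      U <- eng$P_pp %*% U
      out[[n]] <- Mod(U[eng$idx_out, , drop = FALSE])^2
    }
  do.call(rbind, out)
}

# Reverse pass: given dL/dA' (N_o x N_i), return the per-surface gradients
# dL/dphi (list of K numeric vectors of length npix). Uses the Wirtinger
# cotangent g = dL/d(conj u); the adjoint of each propagation is its
# conjugate transpose, and d|u|^2 contributes g += (dL/dA') * u.
engine_backward <- function(eng, fwd, dAp) {
  npix <- eng$npix
  ncols <- ncol(fwd$V[[1L]])
  nv <- fwd$n_vox_out
  inject <- function(n) {
    G <- matrix(0 + 0i, npix, ncols)
    rows <- (n - 1L) * nv + seq_len(nv)
    G[eng$idx_out, ] <- dAp[rows, , drop = FALSE] *
      fwd$W[[n]][eng$idx_out, , drop = FALSE]
    G
  }
  g <- inject(eng$C_o)
  if (eng$C_o > 1L)
    for (n in (eng$C_o - 1L):1L) g <- eng$P_ppH %*% g + inject(n)
  g <- eng$P_out1H %*% g
  dphi <- vector("list", eng$K)
  for (k in eng$K:1L) {
    dphi[[k]] <- -2 * rowSums(Im(Conj(g) * fwd$V[[k]]))
    if (k > 1L) g <- eng$P_gapH %*% (g * exp(-1i * fwd$phases[[k]]))
  }
  dphi
}

# Surface phases (as npix-vectors) for a design at one wavelength, with
# straight-through quantization: returns both the quantized phases used in
# the forward pass and the chain-rule factor dphi/dthickness.
design_phases <- function(design, wavelength, bits) {
  eta <- refractive_index(design$material, wavelength)
  qd <- quantize_domain_of(design)
  scale <- (2 * pi / wavelength) * (eta - 1)
  phases <- lapply(design$latents, function(l) {
    t_s <- thickness_from_latent(l, design$t_max)
    if (qd == "thickness") {
      as.vector(scale * quantize_thickness(t_s, design$t_max, bits))
    } else {
      as.vector(quantize_phase(scale * t_s, bits))
    }
  })
  list(phases = phases, dphi_dt = scale)
}
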