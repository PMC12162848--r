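# Shared in-code fixtures: compact beams and tiny design configurations.

# Centered Gaussian beam on an n x n grid (waist in samples). Chosen compact
# enough that crop-boundary and pad-wrap truncation are negligible for the
# short propagation distances used in the tests.
gaussian_beam <- function(n, waist = 2) {
  xy <- seq_len(n) - (n + 1) / 2
  exp(-outer(xy^2, xy^2, "+") / (2 * waist^2)) + 0i
}

# Design with all-zero thickness (sin(latent) = -1).
flatten_design <- function(design) {
  design$latents <- lapply(design$latents, function(l) l * 0 - pi / 2)
  design
}

# Small 2-plane 2x2 geometry used by the training and sweep tests:
# N_i = N_o = 8, K = 4, N = 4 * N_i * N_o = 256 features.
small_train_geometry <- function(...) {
  processor_geometry(K = 4, M = 8, input_shape = c(2L, 2L, 2L), ...)
}

# Scaled-down replica of the bit-depth-12 study: two planes of 3x3 voxels
# (N_i = N_o = 18), K = 4 surfaces, N = 4 * N_i * N_o = 1296 features,
# geometry from the default layer-width/separation formulas.
reference_fidelity_run <- function(seed, iterations = 1200L, bits = 12) {
  geom <- processor_geometry(K = 4, M = 18, input_shape = c(2L, 3L, 3L))
  A <- random_uniform_target(prod(geom$output_shape), prod(geom$input_shape),
                             seed = seed)
  design <- diffractive_design(geom, seed = seed + 1L)
  trained <- train_design(design, A,
                          train_config(iterations = iterations,
                                       b_train = bits, b_test = bits,
                                       seed = seed, eval_every = 100L))
  list(geometry = geom, target = A, trained = trained)
}
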