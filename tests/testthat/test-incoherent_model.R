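test_that("impulse matrix columns are the vectorized point PSFs on both code paths", {
  geom <- processor_geometry(K = 2, M = 8, input_shape = c(2, 2, 2),
                             output_shape = c(2, 2, 2))
  design <- diffractive_design(geom, seed = 4)
  Ap_op <- impulse_matrix(design, method = "operator")
  Ap_dir <- impulse_matrix(design, method = "direct")
  expect_true(all(Ap_op >= 0))
  expect_lt(max(abs(Ap_op - Ap_dir)), 1e-12)
  # column q is the PSF of voxel q in the plane-major, row-major order
  q <- 0L
  for (n in 1:2) for (l in 1:2) for (m in 1:2) {
    q <- q + 1L
    expect_lt(max(abs(Ap_dir[, q] -
                        vectorize_volume(point_psf(design, n, l, m)))), 1e-14)
  }
})

test_that("free-space PSFs are laterally shift-equivariant", {
  # exact form: a single propagation step commutes with lateral shifts away
  # from the crop boundary
  n <- 24
  u <- matrix(0 + 0i, n, n); u[12, 12] <- 1
  a <- propagate(complex_field(u, wavelength = 1), 1.7)$samples
  u2 <- matrix(0 + 0i, n, n); u2[12, 13] <- 1
  b <- propagate(complex_field(u2, wavelength = 1), 1.7)$samples
  b_rc <- cbind(b[, -1], 0)
  inner <- 3:22
  expect_lt(max(Mod(a[inner, inner] - b_rc[inner, inner])) / max(Mod(a)), 1e-12)
  # cascade form: flat surfaces, re-centered PSFs of neighboring voxels agree
  # over the interior up to crop-boundary truncation of the slowly decaying
  # impulse-response tails
  geom <- processor_geometry(K = 1, M = 32, input_shape = c(1, 5, 5),
                             output_shape = c(1, 32, 32), d_i = 2, d_o = 2,
                             aperture = "open")
  design <- flatten_design(diffractive_design(geom, seed = 1))
  pc <- point_psf(design, 1, 3, 3)[, , 1]
  ps <- point_psf(design, 1, 3, 4)[, , 1]
  ps_rc <- cbind(ps[, -1], 0)
  inner <- 9:24
  expect_lt(max(abs(pc[inner, inner] - ps_rc[inner, inner])) / max(pc), 1e-2)
})

test_that("applying a transformation matches elementwise summation and reshaping", {
  set.seed(11)
  # identity-shaped A returns the input
  i_vol <- array(runif(8), dim = c(2, 2, 2))
  expect_equal(apply_transform(diag(8), i_vol, c(2, 2, 2)), i_vol)
  # basis input selects a column
  A <- matrix(runif(6 * 8), 6, 8)
  e3 <- numeric(8); e3[3] <- 1
  expect_equal(apply_transform(A, e3), A[, 3])
  # independent naive double-loop oracle
  i_vec <- runif(8)
  o_naive <- numeric(6)
  for (p in 1:6) for (q in 1:8) o_naive[p] <- o_naive[p] + A[p, q] * i_vec[q]
  expect_equal(apply_transform(A, i_vec), o_naive, tolerance = 1e-14)
  expect_error(apply_transform(A, runif(5)), "shape")
})

test_that("the optimal scale is the least-squares minimizer", {
  set.seed(2)
  A <- matrix(runif(36), 6, 6)
  expect_equal(optimal_scale(A, A), 1)
  expect_equal(optimal_scale(A, 3.7 * A), 1 / 3.7)
  Ap <- matrix(runif(36), 6, 6)
  # independent oracle: 1-D numerical minimization of ||A - s * Ap||^2
  s_num <- stats::optimize(function(s) sum((A - s * Ap)^2),
                           c(-10, 10), tol = 1e-12)$minimum
  expect_lt(abs(optimal_scale(A, Ap) - s_num), 1e-10)
  expect_error(optimal_scale(A, Ap * 0), "identically zero")
})

test_that("the random-phase ensemble converges to the exact impulse-matrix output", {
  geom <- processor_geometry(K = 2, M = 8, input_shape = c(1, 3, 3))
  design <- diffractive_design(geom, seed = 5)
  Ap <- impulse_matrix(design)
  # a single emitter is exact even at one realization (global phase cancels)
  one <- array(0, dim = c(3, 3, 1)); one[2, 3, 1] <- 0.8
  mc1 <- ensemble_output(design, one, n_phase = 1, seed = 3)
  exact1 <- apply_transform(Ap, one, geom$output_shape)
  expect_lt(max(abs(mc1 - exact1)) / max(exact1), 1e-10)
  # all-zero input gives all-zero output
  expect_true(all(ensemble_output(design, array(0, dim = c(3, 3, 1)),
                                  n_phase = 1, seed = 1) == 0))
  expect_error(ensemble_output(design, one, n_phase = 0), "n_phase")
  # two emitters: Monte-Carlo error within the 5/sqrt(N_phi) envelope
  two <- array(0, dim = c(3, 3, 1)); two[1, 1, 1] <- 0.8; two[3, 2, 1] <- 0.6
  exact <- apply_transform(Ap, two, geom$output_shape)
  mc <- ensemble_output(design, two, n_phase = 2000, seed = 7)
  expect_lt(sqrt(sum((mc - exact)^2)) / sqrt(sum(exact^2)), 5 / sqrt(2000))
  # reproducible under the master seed
  expect_identical(mc, ensemble_output(design, two, n_phase = 2000, seed = 7))
})

test_that("Monte-Carlo error decays as one over the square root of the realization count", {
  geom <- processor_geometry(K = 2, M = 8, input_shape = c(1, 3, 3))
  design <- diffractive_design(geom, seed = 5)
  Ap <- impulse_matrix(design)
  vol <- generate_emitter_volume(geom$input_shape, 5, seed = 9)
  exact <- apply_transform(Ap, vol, geom$output_shape)
  n_phis <- c(10, 100, 1000, 10000)
  mean_log_err <- sapply(n_phis, function(nf) {
    errs <- sapply(1:5, function(s) {
      mc <- ensemble_output(design, vol, n_phase = nf, seed = 100 + s)
      sqrt(sum((mc - exact)^2)) / sqrt(sum(exact^2))
    })
    mean(log(errs))
  })
  slope <- unname(coef(lm(mean_log_err ~ log(n_phis)))[2])
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("incoherent outputs are additive over disjoint emitter sets", {
  geom <- processor_geometry(K = 2, M = 8, input_shape = c(2, 2, 2))
  design <- diffractive_design(geom, seed = 8)
  Ap <- impulse_matrix(design)
  set.seed(13)
  i1 <- array(runif(8) * (runif(8) < 0.5), dim = c(2, 2, 2))
  i2 <- array(runif(8), dim = c(2, 2, 2)) * (i1 == 0)
  o_union <- apply_transform(Ap, i1 + i2, geom$output_shape)
  o_parts <- apply_transform(Ap, i1, geom$output_shape) +
    apply_transform(Ap, i2, geom$output_shape)
  expect_lt(max(abs(o_union - o_parts)), 1e-14)
})

test_that("a trained design has genuinely spatially varying PSFs", {
  geom <- small_train_geometry()
  A <- random_uniform_target(8, 8, seed = 3)
  trained <- train_design(diffractive_design(geom, seed = 4), A,
                          train_config(iterations = 200L, seed = 3,
                                       eval_every = 50L))
  corner <- vectorize_volume(point_psf(trained$design, 1, 1, 1))
  center <- vectorize_volume(point_psf(trained$design, 2, 2, 2))
  rel_l2 <- sqrt(sum((corner - center)^2)) / sqrt(sum(center^2))
  expect_gt(rel_l2, 0.1)
})
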