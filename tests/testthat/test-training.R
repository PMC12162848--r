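test_that("the normalized transformation error matches its direct definition", {
  set.seed(6)
  A <- matrix(runif(25), 5, 5)
  # invariant to positive rescaling of the realized matrix
  for (c_scale in c(0.01, 1, 250)) {
    expect_equal(transformation_error(A, c_scale * A), 0, tolerance = 1e-14)
  }
  # orthogonal realized matrix: sigma = 0 and the loss saturates at 1
  B <- matrix(0, 5, 5); B[1, 1] <- 1
  C <- matrix(0, 5, 5); C[2, 2] <- 1
  expect_equal(transformation_error(B, C), 1)
  # independent oracle: brute-force two-loop evaluation with the scale found
  # by 1-D numerical minimization
  Ap <- matrix(runif(25), 5, 5)
  s <- stats::optimize(function(s) sum((A - s * Ap)^2), c(-10, 10),
                       tol = 1e-14)$minimum
  L_naive <- 0
  for (p in 1:5) for (q in 1:5) L_naive <- L_naive + (A[p, q] - s * Ap[p, q])^2
  L_naive <- L_naive / sum(A^2)
  expect_lt(abs(transformation_error(A, Ap) - L_naive), 1e-12)
  expect_error(transformation_error(A * 0, Ap), "identically zero")
})

test_that("backpropagated gradients match finite differences on a tiny design", {
  geom <- processor_geometry(K = 2, M = 3, input_shape = c(2, 1, 1),
                             output_shape = c(1, 1, 2))
  design <- diffractive_design(geom, seed = 3)
  set.seed(5)
  target <- matrix(runif(4), 2, 2)
  eng <- diffpsf:::build_engine(geom, 1)
  loss_at <- function(d) {
    ph <- diffpsf:::design_phases(d, 1, Inf)
    diffpsf:::loss_and_grad(target, diffpsf:::engine_forward(eng, ph$phases)$Ap)$loss
  }
  ph <- diffpsf:::design_phases(design, 1, Inf)
  fwd <- diffpsf:::engine_forward(eng, ph$phases)
  lg <- diffpsf:::loss_and_grad(target, fwd$Ap)
  dphi <- diffpsf:::engine_backward(eng, fwd, lg$dAp)
  eps <- 1e-6
  for (k in 1:2) for (i in c(1, 5, 9)) {
    up <- design; up$latents[[k]][i] <- up$latents[[k]][i] + eps
    dn <- design; dn$latents[[k]][i] <- dn$latents[[k]][i] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    chain <- ph$dphi_dt * (design$t_max / 2) * cos(design$latents[[k]][i])
    ana <- dphi[[k]][i] * chain
    expect_lt(abs(num - ana) / max(abs(num), 1e-10), 1e-4)
  }
})

test_that("training converges on a self-target immediately and on random targets quickly", {
  geom <- small_train_geometry()
  design <- diffractive_design(geom, seed = 4)
  # the design's own realized matrix as target: zero loss from iteration 0
  self_A <- impulse_matrix(design)
  tr0 <- train_design(design, self_A, train_config(iterations = 1L))
  expect_lt(tr0$trace$loss[1], 1e-12)
  # seeded random target, N = 4 * N_i * N_o, unbounded bit depth
  A <- random_uniform_target(8, 8, seed = 10)
  tr <- train_design(design, A, train_config(iterations = 400L, seed = 10,
                                             eval_every = 100L))
  expect_lt(tr$final$loss, 0.01)
  # the loss trace decreases overall
  expect_lt(tail(tr$trace$loss, 1), tr$trace$loss[1] / 100)
  # mismatched target shape is rejected
  expect_error(train_design(design, matrix(1, 3, 3), train_config(iterations = 1L)),
               "target shape")
})

test_that("coarse training quantization degrades the achievable error", {
  geom <- small_train_geometry()
  design <- diffractive_design(geom, seed = 21)
  A <- random_uniform_target(8, 8, seed = 10)
  tr_inf <- train_design(design, A, train_config(iterations = 300L, seed = 10,
                                                 eval_every = 100L))
  tr_b1 <- train_design(design, A, train_config(iterations = 300L, b_train = 1,
                                                seed = 10, eval_every = 100L))
  expect_gt(tr_b1$final$loss, tr_inf$final$loss)
})

test_that("bit-depth re-evaluation is consistent with training-time quantization", {
  geom <- small_train_geometry()
  design <- diffractive_design(geom, seed = 21)
  A <- random_uniform_target(8, 8, seed = 10)
  tr4 <- train_design(design, A, train_config(iterations = 400L, b_train = 4,
                                              seed = 10, eval_every = 100L))
  # evaluating at the training bit depth reproduces the final loss exactly
  expect_identical(bit_depth_eval(tr4, A, 4)$loss, tr4$final$loss)
  # evaluation above the training bit depth leaves the error nearly constant
  L4 <- tr4$final$loss
  L_inf <- bit_depth_eval(tr4, A, Inf)$loss
  expect_lt(abs(L_inf - L4), 0.1 * L4)
  # evaluation below the training bit depth increases the error
  expect_gte(bit_depth_eval(tr4, A, 1)$loss, L4)
})

test_that("training is reproducible and scale-invariant", {
  geom <- small_train_geometry()
  design <- diffractive_design(geom, seed = 2)
  A <- random_uniform_target(8, 8, seed = 2)
  cfg <- train_config(iterations = 60L, seed = 2, eval_every = 20L)
  tr_a <- train_design(design, A, cfg)
  tr_b <- train_design(design, A, cfg)
  expect_identical(tr_a$trace, tr_b$trace)
  expect_identical(tr_a$final$loss, tr_b$final$loss)
  # doubling the overall optical throughput is absorbed by sigma
  Ap <- tr_a$final$Ap
  expect_equal(transformation_error(A, 2 * Ap), transformation_error(A, Ap),
               tolerance = 1e-12)
})
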