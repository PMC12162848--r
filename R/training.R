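# Gradient-based optimization of surface latents against the normalized
# transformation loss, plus bit-depth re-evaluation of trained designs.

#' Normalized transformation error
#'
#' `L = sum((A - sigma * A')^2) / sum(A^2)` with `sigma` the closed-form
#' optimal scale from [optimal_scale()]. Invariant to positive rescaling of
#' `A'`; equals 0 iff `A'` is proportional to `A` and 1 when `A` and `A'` are
#' orthogonal (`sigma = 0`).
#'
#' @param A Target transformation matrix.
#' @param Ap Realized transformation matrix, same shape.
#' @return Nonnegative scalar loss.
#' @export
transformation_error <- function(A, Ap) {
  if (!all(dim(A) == dim(Ap))) stop("shape mismatch")
  denom <- sum(A^2)
  if (denom == 0) stop("target transformation is identically zero")
  sigma <- if (sum(Ap^2) == 0) 0 else optimal_scale(A, Ap)
  sum((A - sigma * Ap)^2) / denom
}

# Loss and its gradient with respect to A'. Because sigma minimizes the loss,
# dL/dsigma = 0 at the optimum and the envelope theorem makes the partial
# derivative at fixed sigma exact.
loss_and_grad <- function(A, Ap) {
  denom <- sum(A^2)
  sAp2 <- sum(Ap^2)
  sigma <- if (sAp2 == 0) 0 else sum(A * Ap) / sAp2
  R <- A - sigma * Ap
  list(loss = sum(R^2) / denom, dAp = -2 * sigma * R / denom, sigma = sigma)
}

#' Training configuration
#'
#' @param iterations Number of gradient steps (>= 1).
#' @param lr Base learning rate of the adaptive-moment (Adam) optimizer.
#' @param lr_schedule `"cosine"` (decay to 0 over the run) or `"constant"`.
#' @param b_train Bit depth applied during training (straight-through
#'   gradient: quantized forward pass, identity backward).
#' @param b_test Bit depth applied in the final evaluation.
#' @param seed Seed controlling any training-time randomness.
#' @param lambda_weights Optional per-wavelength loss weights (default equal).
#' @param eval_every Record the loss every this many iterations (the loss at
#'   every iteration is computed anyway; this thins the returned trace to one
#'   row per `eval_every` plus the first and last).
#' @param beta1,beta2,eps Adam moment parameters.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 5000L, lr = 0.02,
                         lr_schedule = c("cosine", "constant"),
                         b_train = Inf, b_test = b_train, seed = 1L,
                         lambda_weights = NULL, eval_every = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(iterations >= 1L, lr > 0)
  structure(list(iterations = as.integer(iterations), lr = lr,
                 lr_schedule = lr_schedule,
                 policy = bit_depth_policy(b_train, b_test), seed = seed,
                 lambda_weights = lambda_weights,
                 eval_every = as.integer(eval_every),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "train_config")
}

# Normalize the target argument to a named-by-index list, one matrix per
# design wavelength.
as_target_list <- function(target, n_wavelengths) {
  if (is.matrix(target)) target <- list(target)
  if (length(target) != n_wavelengths)
    stop("need one target matrix per design wavelength")
  target
}

#' Train a diffractive design against a target transformation
#'
#' Minimizes the normalized transformation error by adaptive-moment gradient
#' descent on the surface latents. Each iteration recomputes the realized
#' matrix `A'` through the exact (deterministic) impulse-response cascade and
#' backpropagates through the squared-modulus detection, the propagation
#' steps (adjoint = conjugate-transpose operator) and the phase/thickness
#' parametrization; bounded training bit depths use a straight-through
#' gradient. Multiwavelength losses are averaged (or combined with
#' `lambda_weights`).
#'
#' @param design A [diffractive_design] (its latents are the starting point).
#' @param target Target matrix `A`, or a list of per-wavelength matrices for
#'   multiwavelength designs.
#' @param config A [train_config].
#' @param pad_factor FFT zero-padding factor for the propagation operators.
#' @param engines Optional precomputed engines (one per wavelength), reused
#'   across calls with identical geometry.
#' @return An object of class `trained_design`: the design with optimized
#'   latents, the loss trace (`data.frame` with iteration, loss, lr), the
#'   final evaluation at `b_test` (loss, `sigma`, `Ahat`, max elementwise
#'   `|A - Ahat|`), and the config echo.
#' @export
train_design <- function(design, target, config = train_config(),
                         pad_factor = 2L, engines = NULL) {
  geom <- design$geometry
  wavelengths <- geom$wavelengths
  n_w <- length(wavelengths)
  targets <- as_target_list(target, n_w)
  n_vox_out <- prod(geom$output_shape)
  for (A in targets)
    if (nrow(A) != n_vox_out || ncol(A) != prod(geom$input_shape))
      stop("target shape does not match the geometry voxel grids")
  weights <- config$lambda_weights %||% rep(1 / n_w, n_w)
  stopifnot(length(weights) == n_w)
  if (is.null(engines))
    engines <- lapply(wavelengths, function(l) build_engine(geom, l, pad_factor))
  b_tr <- config$policy$b_train
  K <- geom$K; M <- geom$M
  latents <- design$latents
  mom1 <- lapply(seq_len(K), function(k) matrix(0, M, M))
  mom2 <- lapply(seq_len(K), function(k) matrix(0, M, M))
  trace_it <- integer(0); trace_loss <- numeric(0); trace_lr <- numeric(0)
  Tmax <- config$iterations
  for (it in seq_len(Tmax)) {
    dlat <- lapply(seq_len(K), function(k) matrix(0, M, M))
    loss <- 0
    work_design <- design; work_design$latents <- latents
    dthick_chain <- lapply(latents, function(l) (design$t_max / 2) * cos(l))
    for (w in seq_len(n_w)) {
      ph <- design_phases(work_design, wavelengths[w], b_tr)
      fwd <- engine_forward(engines[[w]], ph$phases)
      lg <- loss_and_grad(targets[[w]], fwd$Ap)
      loss <- loss + weights[w] * lg$loss
      if (any(!is.finite(lg$dAp)))
        stop(sprintf("training diverged (non-finite loss) at iteration %d; lr=%g",
                     it, config$lr))
      dphi <- engine_backward(engines[[w]], fwd, weights[w] * lg$dAp)
      for (k in seq_len(K))
        dlat[[k]] <- dlat[[k]] +
          matrix(dphi[[k]], M, M) * ph$dphi_dt * dthick_chain[[k]]
    }
    if (!is.finite(loss))
      stop(sprintf("training diverged (loss = %g) at iteration %d; lr=%g",
                   loss, it, config$lr))
    lr_t <- if (config$lr_schedule == "cosine")
      config$lr / 2 * (1 + cos(pi * (it - 1) / Tmax)) else config$lr
    bc1 <- 1 - config$beta1^it; bc2 <- 1 - config$beta2^it
    for (k in seq_len(K)) {
      mom1[[k]] <- config$beta1 * mom1[[k]] + (1 - config$beta1) * dlat[[k]]
      mom2[[k]] <- config$beta2 * mom2[[k]] + (1 - config$beta2) * dlat[[k]]^2
      latents[[k]] <- latents[[k]] -
        lr_t * (mom1[[k]] / bc1) / (sqrt(mom2[[k]] / bc2) + config$eps)
    }
    if (it == 1L || it == Tmax || it %% config$eval_every == 0L) {
      trace_it <- c(trace_it, it); trace_loss <- c(trace_loss, loss)
      trace_lr <- c(trace_lr, lr_t)
    }
  }
  design$latents <- latents
  final <- evaluate_design(design, targets, config$policy$b_test,
                           engines = engines, weights = weights)
  structure(list(design = design, config = config,
                 trace = data.frame(iteration = trace_it, loss = trace_loss,
                                    lr = trace_lr),
                 final = final),
            class = "trained_design")
}

#' Evaluate a design against a target at a given bit depth
#'
#' Recomputes the realized transformation with surfaces quantized at
#' `b_test` (no retraining) and reports the loss, the optimal scale, the
#' scaled realized matrix `Ahat`, and the maximum elementwise deviation
#' `max |A - Ahat|`.
#'
#' @param design A [diffractive_design].
#' @param target Target matrix or per-wavelength list.
#' @param b_test Evaluation bit depth.
#' @param engines Optional precomputed engines.
#' @param weights Optional per-wavelength loss weights.
#' @param pad_factor FFT zero-padding factor.
#' @return List with `loss`, and per-wavelength `sigma`, `Ap`, `Ahat`,
#'   `max_abs_err` (scalars/matrices for single-wavelength designs, lists
#'   otherwise, plus `per_wavelength_loss`).
#' @export
evaluate_design <- function(design, target, b_test = Inf, engines = NULL,
                            weights = NULL, pad_factor = 2L) {
  geom <- design$geometry
  wavelengths <- geom$wavelengths
  n_w <- length(wavelengths)
  targets <- as_target_list(target, n_w)
  weights <- weights %||% rep(1 / n_w, n_w)
  if (is.null(engines))
    engines <- lapply(wavelengths, function(l) build_engine(geom, l, pad_factor))
  per <- lapply(seq_len(n_w), function(w) {
    ph <- design_phases(design, wavelengths[w], b_test)
    Ap <- engine_forward(engines[[w]], ph$phases)$Ap
    sigma <- optimal_scale(targets[[w]], Ap)
    Ahat <- sigma * Ap
    list(loss = transformation_error(targets[[w]], Ap), sigma = sigma,
         Ap = Ap, Ahat = Ahat, max_abs_err = max(abs(targets[[w]] - Ahat)))
  })
  loss <- sum(vapply(seq_len(n_w), function(w) weights[w] * per[[w]]$loss,
                     numeric(1)))
  if (n_w == 1L) {
    c(list(loss = loss, b_test = b_test), per[[1L]][-1L],
      list(per_wavelength_loss = per[[1L]]$loss))
  } else {
    list(loss = loss, b_test = b_test,
         sigma = lapply(per, `[[`, "sigma"),
         Ap = lapply(per, `[[`, "Ap"),
         Ahat = lapply(per, `[[`, "Ahat"),
         max_abs_err = max(vapply(per, `[[`, numeric(1), "max_abs_err")),
         per_wavelength_loss = vapply(per, `[[`, numeric(1), "loss"))
  }
}

#' Re-evaluate a trained design at a different test bit depth
#'
#' @param trained A `trained_design` from [train_design()].
#' @param target The target used in training.
#' @param b_test Evaluation bit depth.
#' @param ... Passed to [evaluate_design()].
#' @return The [evaluate_design()] result at `b_test`.
#' @export
bit_depth_eval <- function(trained, target, b_test, ...) {
  stopifnot(inherits(trained, "trained_design"))
  evaluate_design(trained$design, target, b_test, ...)
}

#' @export
print.trained_design <- function(x, ...) {
  cat(sprintf("<trained_design: %d iterations, final loss %.4g (b_test=%s), max|A-Ahat| %.4g>\n",
              x$config$iterations, x$final$loss,
              format(x$final$b_test), x$final$max_abs_err))
  invisible(x)
}
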