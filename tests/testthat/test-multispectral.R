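# Spectrally and spatially varying PSFs: one shared-thickness processor
# trained against per-wavelength Kronecker targets (visible band, with and
# without water immersion of the emitters).

vis_lams <- c(0.580, 0.600, 0.620)                       # micrometres
vis_material <- dispersion(vis_lams, c(1.4587, 1.4580, 1.4574))
water <- dispersion(vis_lams, c(1.3328, 1.3320, 1.3320))

test_that("one physical surface stack yields dispersion-consistent multiwavelength designs", {
  geom <- processor_geometry(K = 2, M = 6, wavelengths = vis_lams,
                             input_shape = c(1L, 2L, 2L))
  des <- diffractive_design(geom, material = vis_material, seed = 3)
  # default maximum thickness: full 2*pi depth at the most demanding lambda
  expect_equal(des$t_max, max(vis_lams / (c(1.4587, 1.4580, 1.4574) - 1)))
  # the same thickness map produces wavelength-scaled phases
  s1 <- design_surfaces(des)[[1L]]
  t_s <- surface_thickness(s1)
  for (l in vis_lams) {
    eta <- refractive_index(vis_material, l)
    expect_equal(surface_phase(s1, l, quantize_domain = "thickness"),
                 (2 * pi / l) * (eta - 1) * t_s)
  }
  # thickness-domain quantization keeps one physical device across lambdas:
  # quantized phases at different lambdas stay proportional to (eta-1)/lambda
  ph1 <- surface_phase(s1, vis_lams[1], bits = 4, quantize_domain = "thickness")
  ph3 <- surface_phase(s1, vis_lams[3], bits = 4, quantize_domain = "thickness")
  r13 <- ((1.4587 - 1) / vis_lams[1]) / ((1.4574 - 1) / vis_lams[3])
  expect_equal(ph1, ph3 * r13, tolerance = 1e-12)
})

test_that("a multispectral snapshot imager converges with low spectral cross-talk", {
  layout <- superpixel_layout(c(1L, 2L, 2L), n_wavelengths = 3L)
  targets <- multispectral_target(layout)
  geom <- processor_geometry(K = 4, M = 12, wavelengths = vis_lams,
                             input_shape = c(1L, 2L, 2L),
                             output_shape = layout$output_shape)
  des <- diffractive_design(geom, material = vis_material, seed = 6)
  tr <- train_design(des, targets, train_config(iterations = 1500L, seed = 6,
                                                eval_every = 500L))
  expect_lt(tr$final$loss, 0.01)
  expect_length(tr$final$per_wavelength_loss, 3L)
  # energy routed to pixels dedicated to other wavelengths stays below 5%
  expect_lt(spectral_crosstalk(tr$final$Ap, layout), 0.05)
  # demultiplexing the simulated detector frame recovers the emitters with
  # the right spectral assignment
  vol <- generate_emitter_volume(geom$input_shape, 2, n_channels = 3, seed = 2)
  frame <- matrix(0, 4, 4)
  for (w in 1:3) {
    o_w <- apply_transform(tr$final$Ahat[[w]],
                           vectorize_volume(vol$intensity * (vol$channel == w)))
    frame <- frame + unvectorize_volume(o_w, layout$output_shape)[, , 1L]
  }
  imgs <- demultiplex(frame, layout)
  for (w in 1:3) {
    truth <- vol$intensity * (vol$channel == w)
    expect_lt(max(abs(imgs[, , 1L, w] - truth[, , 1L])), 0.05)
  }
})

test_that("an imager trained in free space fails under unmodeled water immersion", {
  layout <- superpixel_layout(c(1L, 2L, 2L), n_wavelengths = 3L)
  targets <- multispectral_target(layout)
  geom <- processor_geometry(K = 4, M = 8, wavelengths = vis_lams,
                             input_shape = c(1L, 2L, 2L),
                             output_shape = layout$output_shape)
  des <- diffractive_design(geom, material = vis_material, seed = 6)
  tr <- train_design(des, targets, train_config(iterations = 600L, seed = 6,
                                                eval_every = 200L))
  # blind test with the emitters immersed in water: the input-side medium
  # dispersion deviates from training and the transformation degrades badly
  geom_w <- processor_geometry(K = 4, M = 8, wavelengths = vis_lams,
                               input_shape = c(1L, 2L, 2L),
                               output_shape = layout$output_shape,
                               medium = water, medium_extent = "input")
  blind <- tr$design; blind$geometry <- geom_w
  expect_gt(evaluate_design(blind, targets)$loss, 10 * tr$final$loss)
  # retraining with the water dispersion known restores the performance
  tr_w <- train_design(diffractive_design(geom_w, material = vis_material,
                                          seed = 7),
                       targets, train_config(iterations = 600L, seed = 7,
                                             eval_every = 200L))
  expect_lt(tr_w$final$loss, 0.05)
  # the medium only alters the input-side segments
  expect_equal(diffpsf:::medium_index_at(geom_w, vis_lams[1]), 1.3328)
  expect_equal(diffpsf:::medium_index_at(geom, vis_lams[1]), 1)
})
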