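---
title: "Engineering spatially varying 3D PSFs with incoherent diffractive processors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering spatially varying 3D PSFs with incoherent diffractive processors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A spatially incoherent diffractive processor is a cascade of `K` thin,
passive, phase-only surfaces separated by free space. Emitters (for example,
fluorophores) fill a voxelized input volume of `C_i` planes of `H_i x W_i`
diffraction-limited pixels; a detector volume is discretized the same way.
Because independent emitters carry mutually random, time-varying phases, all
interference cross-terms time-average to zero, and the system is *linear in
intensity*:

\[ \mathbf{o} = \mathbf{A}\,\mathbf{i}, \]

where `i` and `o` are the vectorized input and output intensities and the
`q`-th column of the nonnegative `N_o x N_i` matrix `A` is the vectorized 3D
point spread function (PSF) of input voxel `q`. Unlike pupil-plane phase
masks, whose PSF is laterally invariant, the columns of `A` may be chosen
*arbitrarily and independently* — spatially varying 3D PSFs — provided the
processor has enough optimizable features. Empirically the transformation
error collapses once the feature count `N` reaches about `2 N_i N_o` for
a sufficiently deep (`K >= 4`) cascade; the factor 2 reflects that phase-only
features carry half the degrees of freedom of complex-valued ones.

Two assumptions make the model linear, and they bound its scope: emitters
neither shadow nor re-excite one another, and emitted light is not scattered
again inside the sample. Densely labeled or strongly scattering volumes
violate both, as they do for most established 3D fluorescence methods.

### Coherent building block

For one input plane and one wavelength the field propagates coherently:
modulation at surface `k` multiplies the field by `exp(i * phi_k(x, y))`, and
the gaps are bridged by the band-limited angular spectrum method
(`propagate()`): FFT, multiplication by

\[ H(f_x,f_y;d)=\exp\!\big(i\,2\pi d/\lambda\,\sqrt{1-(\lambda f_x)^2-(\lambda f_y)^2}\big) \]

for propagating frequencies and exactly 0 beyond the evanescent cutoff, then
inverse FFT. The incoherent intensity model follows in two equivalent forms:

* **impulse matrix** (`impulse_matrix()`): propagate a unit impulse from every
  input voxel and stack the squared moduli — exact and deterministic, used
  for training;
* **random-phase ensemble** (`ensemble_output()`): average the output
  intensities of `N_phi` coherent realizations `sqrt(I) e^{i phi_r}` with
  i.i.d. uniform(0, 2*pi) phases, drawn independently per input plane
  (cross-plane incoherence) and per wavelength channel (spectral
  incoherence). Its error against the impulse matrix decays as
  `1/sqrt(N_phi)`; we default to `N_phi = 10^4` for validation runs and never
  use the ensemble during training.

## Geometry and its parameters

All lengths share the unit of the design wavelength(s). Defaults follow the
diffraction-limited discretization of the volumes:

| parameter | meaning | default |
|---|---|---|
| `pitch` | lateral sampling interval and feature pitch | `0.53 * lambda` |
| `d_pp` | plane-to-plane distance inside the volumes | `2.67 * lambda` |
| `W` | layer width, `M * pitch` for `M x M` features | — |
| `d` | surface-to-surface gap | `(W * pitch / lambda) * sqrt(1 - (lambda / (2 * pitch))^2)` |
| `d_i`, `d_o` | farthest input/output plane to first/last surface | NA-matched (below) |

The separation formula keeps the optical connectivity between successive
layers constant as `N` (hence `W`) changes, so feature-count sweeps compare
architectures rather than geometries. The distances `d_i = d_o` set the
input/output numerical aperture `NA = eta_m * sin(atan((W/2)/d_i))` and with
it the axial resolution limit `2 * lambda / NA^2`. The reference
configuration (`W = 57 lambda`, `d_i = 21 lambda`) has `NA = 0.81` and an
axial limit of `3.05 lambda`; our default `d_i` preserves that NA for any
layer width (clamped so the input volume always fits, `d_i >= (C_i - 1) *
d_pp`). Axial convention: input plane 1 is farthest from the processor,
output plane `C_o` is farthest on the detector side — these farthest planes
are what define `d_i` and `d_o` and hence the NA.

Voxel vectorization is plane-major, then row-major within a plane
(`vectorize_volume()`), which fixes the row/column order of every
transformation matrix.

### Surfaces, thickness and bit depth

Each surface is parametrized by an unconstrained latent map through
`t = (t_max / 2)(sin(t_latent) + 1)`, confining the physical thickness to
`[0, t_max]` while keeping the optimization unconstrained. The phase delay is
`phi = (2 pi / lambda)(eta(lambda) - 1) t` with `eta` from the material
dispersion table. The default `t_max = lambda / (eta - 1)` gives exactly a
`2 pi` modulation depth (for multiwavelength designs, `max_i lambda_i /
(eta(lambda_i) - 1)`, so the most demanding wavelength still reaches full
depth). Latents initialize i.i.d. uniform(-pi, pi): thickness is mid-range on
average and stays away from the saturated regions of the sine.

A bit depth `b` means `2^b` uniformly spaced modulation levels. Monochrome
designs quantize *phase* (wrapped to `[0, 2 pi)`, nearest level, wrap-around
at the top). Multiwavelength designs quantize the shared physical *thickness*
to `2^b` levels in `[0, t_max]` instead, because one fabricated device must
be consistent across wavelengths; at the wavelength whose modulation depth is
exactly `2 pi` the two prescriptions coincide. During training a bounded
`b_train` uses a straight-through gradient: the forward pass sees the
quantized surface, the backward pass treats the quantizer as the identity.
This is the minimal differentiable choice and reproduces the characteristic
robustness pattern: evaluating a `b_train`-trained design at any `b_test >=
b_train` leaves the error nearly unchanged, while `b_test < b_train` degrades
it sharply.

### Aperture and immersion medium

Light falling outside the `W x W` extent of a surface is blocked (opaque
mount). This matches the premise of the connectivity-based separation
formula; a transparent surround is available as `aperture = "open"` and is
used by the tests that compare a flat cascade against a single free-space
propagation. When a dispersive medium immerses the emitters (water, for the
visible-band demonstrations), it fills the input volume from the farthest
input plane up to the first surface (`medium_extent = "input"`); propagation
there uses the effective wavelength `lambda / eta_m(lambda)`. Gaps between
surfaces and the detector side remain free space. Training with
`eta_m = 1` and blindly testing under water immersion degrades the
transformation badly; retraining with the water dispersion built into the
forward model restores it.

## Optimization

Training minimizes the scale-invariant transformation error

\[ \mathcal{L}=\frac{\sum_{p,q}(A[p,q]-\sigma_A A'[p,q])^2}{\sum_{p,q}A[p,q]^2},
\qquad \sigma_A=\frac{\sum A\,A'}{\sum A'^2}, \]

where `A'` is the realized impulse matrix and `sigma_A` the closed-form
least-squares scale absorbing the overall optical throughput (PSF columns
are *not* normalized; they carry the physical throughput). Because `sigma_A`
minimizes the loss, the envelope theorem makes the partial derivative at
fixed `sigma_A` exact, which simplifies the backward pass.

R has no automatic differentiation, so the package implements reverse-mode
gradients directly. The structure of the cascade makes this natural:

* every free-space step is a linear operator whose adjoint is the
  conjugate-transpose — equivalently, propagation by `-d`;
* detection contributes `d|u|^2` terms; modulation contributes
  `dL/dphi = -2 Im(conj(g) u)` with `g` the Wirtinger cotangent;
* the latent chain rule multiplies by `(2 pi / lambda)(eta - 1)` and
  `(t_max / 2) cos(t_latent)`.

A finite-difference check on a tiny design (3x3 features, 2 voxels) agrees
with the backpropagated gradients to better than `1e-4` relative and is part
of the test suite.

For the small grids of inverse design it is faster to precompute each
propagation step as a dense complex operator (its columns are the
`propagate()` responses of basis impulses, so the operator and FFT paths
agree to round-off by construction) and push all `N_i` impulse fields through
the cascade as one BLAS matrix product per step. The FFT path remains the
user-facing forward model; the tests cross-check both.

The optimizer is adaptive-moment gradient descent (Adam, `lr = 0.02`,
`beta = 0.9/0.999`) with a cosine decay of the learning rate to zero over the
run. Multiwavelength losses combine as an unweighted mean by default
(`lambda_weights` overrides). Runs are bitwise reproducible under a fixed
seed on a single thread, and `save_design()` serializes every
floating-point quantity at 17 significant digits so that a reloaded design
replays its loss trace bit-identically.

## Imaging targets and superpixel multiplexing

Snapshot 3D imaging assigns every input voxel its own detector pixel on a
single output plane: pixels are grouped into `H_i x W_i` superpixels of
`s x s` constituents, `s = ceiling(sqrt(C_i * n_lambda))`, and the
(plane, wavelength) pairs pack row-major into the block. The target `A` is
then a Kronecker-delta map — a permutation matrix when the block is exactly
filled. Output pixels assigned to *other* wavelengths are explicit zero
targets, so the loss actively penalizes spectral leakage instead of assuming
it away; for converged designs with `N` comfortably above `2 N_i N_o
n_lambda` the residual cross-talk (energy on other-wavelength pixels) falls
below 5%. Image formation and readout never involve arithmetic beyond the
optical transform itself: `demultiplex()` is a pure index rearrangement,
exactly inverse to `multiplex()`.

## What the synthetic generator does and does not emulate

`generate_emitter_volume()` produces sparse volumes of independent emitters
with intensities uniform(0.5, 1) and optional per-emitter wavelength labels —
the "distinct emitter configuration per plane" scenes of the snapshot
demonstrations. It emulates independence, sparsity and spectral labeling; it
does not emulate photon noise, detector noise, emitter blinking or bleaching,
refractive-index heterogeneity, or any emitter-to-emitter coupling. Passing
tests therefore demonstrate the correctness of the forward model and
optimizer under the model's own assumptions, not robustness of a design to
experimental non-idealities such as misalignment or fabrication error.

## Numerical choices

* **Zero padding.** Fields are padded by an integer factor (default 2,
  linear-convolution regime) before the FFT; results change by less than
  `1e-6` when the factor is raised to 3 for well-contained fields. The padded
  frequency grid has spacing `1/(n_pad * pitch)` in standard DFT layout.
* **Evanescent cutoff.** `H` is exactly 0 at and beyond `f_x^2 + f_y^2 =
  1/lambda^2`; propagating factors have unit modulus, so energy within the
  band is conserved.
* **Back-propagation.** Negative distances use the conjugate transfer
  function, enabling exact round-trip tests.
* **Output readout.** Output intensities are sampled at grid points; no
  pixel-area integration.
* **Degenerate inputs.** An identically zero realized matrix makes
  `sigma_A` undefined (error); an identically zero target makes the loss
  undefined (error); `quantize_phase` rejects `b < 1`; sweep points whose
  feature count admits no integer grid at least as large as the voxel extent
  are skipped with a warning, after snapping `N` to the nearest feasible
  `K * M^2`.
* **Seeds.** One master seed expands deterministically: per-point seeds in
  sweeps (`base + index`), per-(channel, plane) streams in the ensemble
  (`seed + 1000 * (plane - 1) + 100000 * (channel - 1)`).

## Problem sizes used in the shipped studies

The packaged tests and the acceptance script run scaled-down replicas chosen
to exercise every mechanism while remaining desk-sized: the bit-depth-12
fidelity study uses two planes of 3x3 voxels (`N_i = N_o = 18`) with `K = 4`
and `N = 4 N_i N_o = 1296` features trained for at most a few thousand
iterations; trend sweeps (feature count, depth, axial sampling, bit depth)
use two planes of 2x2 voxels with 400-iteration runs; the multispectral
imager uses one 2x2 plane at three visible wavelengths. At these sizes the
full suite and the acceptance script each complete in minutes on one CPU
core. The qualitative conclusions — error collapse near `N = 2 N_i N_o`,
the depth advantage of `K = 4` over `K = 2`, monotone error growth as `d_pp`
shrinks below `2 lambda / NA^2`, bit-depth robustness for `b_test >=
b_train`, sub-5% spectral cross-talk — reproduce at this scale; absolute
error floors at full scale depend on the (much larger) voxel counts used
there.

## Known limitations

Scalar diffraction only (no polarization or vectorial effects), phase-only
passive surfaces (no gain, no trainable absorption), no partial temporal
coherence within a wavelength channel, no absorbing media, and no
misalignment-aware training. The dense-operator engine is intended for
inverse-design grids (hundreds of features per side at most); very large
forward simulations should use the FFT path.
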