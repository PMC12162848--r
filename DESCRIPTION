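Package: diffpsf
Title: Universal 3D Point Spread Function Engineering with Spatially
    Incoherent Diffractive Optical Processors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and gradient-based inverse design of spatially
    incoherent diffractive optical processors that synthesize arbitrary
    sets of spatially (and spectrally) varying 3D point spread functions
    between a voxelized emitter volume and a detector volume. Implements
    band-limited angular-spectrum scalar diffraction, phase-only
    diffractive surfaces with dispersion-aware thickness parametrization
    and bit-depth quantization, the incoherent intensity forward model
    (exact impulse-response transformation matrices and a Monte-Carlo
    random-phase ensemble), target transformations for snapshot 3D and
    multispectral 3D imaging with superpixel multiplexing, and an
    adjoint-based optimizer with sweep harnesses over feature count,
    surface count, bit depth and axial geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
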