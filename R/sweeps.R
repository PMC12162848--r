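# Sweep harnesses that regenerate the trend studies (error versus feature
# count, surface count, bit depth, axial geometry) at configurable scale.

# Nearest feasible feature count for a sweep point: N must equal K * M^2 for
# integer M >= the lateral voxel extent.
nearest_feasible_M <- function(N, K, min_M) {
  M <- round(sqrt(N / K))
  if (M < min_M) NA_integer_ else as.integer(M)
}

#' Sweep a design axis and record the final transformation error
#'
#' Trains one fresh design per axis value and records the final loss at
#' `b_test`. The same target matrix is shared across all points of a sweep
#' (isolating the architecture effect), while each point gets a fresh,
#' logged seed for its latent initialization. For the `N` and `K` axes the
#' geometry is rebuilt per point with the nearest feasible `M` (layer width
#' and separation follow the `W = M * pitch` and connectivity formulas);
#' infeasible points are skipped with a warning.
#'
#' @param axis One of `"N"`, `"K"`, `"b"`, `"d_pp"`, `"d_io"`.
#' @param values Sorted numeric vector of axis values (`d_io` sweeps set
#'   `d_i = d_o = value`).
#' @param base_geometry A [processor_geometry] providing every parameter not
#'   swept.
#' @param target Shared target matrix (defaults to a seeded random-uniform
#'   target of the right shape).
#' @param config Base [train_config]; per-point seeds are
#'   `config$seed + point index`.
#' @param material Surface material.
#' @param pad_factor FFT zero-padding factor.
#' @return `data.frame` with columns `axis`, `value`, `N`, `K`, `M`, `seed`,
#'   `loss` (final transformation error at `b_test`), one row per trained
#'   point; skipped points are absent.
#' @export
sweep_design <- function(axis = c("N", "K", "b", "d_pp", "d_io"), values,
                         base_geometry, target = NULL,
                         config = train_config(iterations = 400L),
                         material = 1.6518, pad_factor = 2L) {
  axis <- match.arg(axis)
  if (is.unsorted(values)) stop("'values' must be sorted")
  g0 <- base_geometry
  min_M <- max(g0$input_shape[2:3], g0$output_shape[2:3])
  if (is.null(target))
    target <- random_uniform_target(prod(g0$output_shape),
                                    prod(g0$input_shape),
                                    seed = config$seed)
  rows <- list()
  for (i in seq_along(values)) {
    v <- values[i]
    geom <- g0
    cfg <- config
    if (axis == "N") {
      M <- nearest_feasible_M(v, g0$K, min_M)
      if (is.na(M)) { warning(sprintf("N = %g infeasible; skipped", v)); next }
      geom <- processor_geometry(g0$K, M, wavelengths = g0$wavelengths,
                                 input_shape = g0$input_shape,
                                 output_shape = g0$output_shape,
                                 pitch = g0$pitch, d_pp = g0$d_pp,
                                 medium = g0$medium,
                                 medium_extent = g0$medium_extent,
                                 aperture = g0$aperture)
    } else if (axis == "K") {
      M <- nearest_feasible_M(g0$N, v, min_M)
      if (is.na(M)) { warning(sprintf("K = %g infeasible; skipped", v)); next }
      geom <- processor_geometry(as.integer(v), M, wavelengths = g0$wavelengths,
                                 input_shape = g0$input_shape,
                                 output_shape = g0$output_shape,
                                 pitch = g0$pitch, d_pp = g0$d_pp,
                                 medium = g0$medium,
                                 medium_extent = g0$medium_extent,
                                 aperture = g0$aperture)
    } else if (axis == "b") {
      cfg$policy <- bit_depth_policy(v, v)
    } else if (axis == "d_pp") {
      geom <- processor_geometry(g0$K, g0$M, wavelengths = g0$wavelengths,
                                 input_shape = g0$input_shape,
                                 output_shape = g0$output_shape,
                                 pitch = g0$pitch, d = g0$d, d_i = g0$d_i,
                                 d_o = g0$d_o, d_pp = v, medium = g0$medium,
                                 medium_extent = g0$medium_extent,
                                 aperture = g0$aperture)
    } else if (axis == "d_io") {
      geom <- processor_geometry(g0$K, g0$M, wavelengths = g0$wavelengths,
                                 input_shape = g0$input_shape,
                                 output_shape = g0$output_shape,
                                 pitch = g0$pitch, d = g0$d, d_i = v,
                                 d_o = v, d_pp = g0$d_pp, medium = g0$medium,
                                 medium_extent = g0$medium_extent,
                                 aperture = g0$aperture)
    }
    seed_i <- config$seed + i
    design <- diffractive_design(geom, material = material, seed = seed_i)
    tr <- train_design(design, target, cfg, pad_factor = pad_factor)
    rows[[length(rows) + 1L]] <-
      data.frame(axis = axis, value = v, N = geom$N, K = geom$K, M = geom$M,
                 seed = seed_i, loss = tr$final$loss)
  }
  do.call(rbind, rows) %||% data.frame()
}
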