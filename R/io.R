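# Fixtures, persistence and run manifests.

#' Voxelized emitter volume
#'
#' Nonnegative 3D intensity grid `(H_i, W_i, C_i)` with an optional per-voxel
#' wavelength-channel label (integer index into the design wavelengths) for
#' multispectral scenes.
#'
#' @param intensity Nonnegative array `(H, W, C)`.
#' @param channel Optional integer array of the same shape assigning each
#'   voxel to a wavelength channel (default all 1).
#' @param n_channels Number of wavelength channels.
#' @return An object of class `emitter_volume`.
#' @export
emitter_volume <- function(intensity, channel = NULL, n_channels = 1L) {
  stopifnot(length(dim(intensity)) == 3L, all(intensity >= 0))
  if (is.null(channel)) channel <- array(1L, dim = dim(intensity))
  stopifnot(all(dim(channel) == dim(intensity)),
            all(channel >= 1L), all(channel <= n_channels))
  structure(list(intensity = intensity, channel = channel,
                 n_channels = as.integer(n_channels)),
            class = "emitter_volume")
}

as_emitter_volume <- function(x) {
  if (inherits(x, "emitter_volume")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(emitter_volume(x))
  stop("cannot interpret input as an emitter volume")
}

intensity_of <- function(x) as_emitter_volume(x)$intensity

# Intensity restricted to one wavelength channel.
channel_intensity <- function(volume, w) {
  volume$intensity * (volume$channel == w)
}

# 17 significant digits round-trip an IEEE double exactly through text.
num17 <- function(x) sprintf("%.17g", x)

#' Generate a sparse random emitter volume
#'
#' `n_emitters` voxels are chosen uniformly at random (without replacement)
#' and given intensities drawn uniform(0.5, 1); for multispectral volumes
#' each emitter is assigned a uniformly random wavelength channel.
#' Reproducible under the seed.
#'
#' @param input_shape Integer `c(C_i, H_i, W_i)`.
#' @param n_emitters Number of emitting voxels
#'   (`0 <= n_emitters <= C_i * H_i * W_i`).
#' @param n_channels Number of wavelength channels (default 1).
#' @param seed Integer seed.
#' @return An [emitter_volume].
#' @export
generate_emitter_volume <- function(input_shape, n_emitters, n_channels = 1L,
                                    seed = 1L) {
  stopifnot(length(input_shape) == 3L)
  n_vox <- prod(input_shape)
  if (n_emitters < 0L || n_emitters > n_vox)
    stop("emitter count exceeds the number of voxels")
  set.seed(seed)
  intensity <- array(0, dim = c(input_shape[2L], input_shape[3L], input_shape[1L]))
  channel <- array(1L, dim = dim(intensity))
  if (n_emitters > 0L) {
    pos <- sample.int(n_vox, n_emitters)
    intensity[pos] <- stats::runif(n_emitters, 0.5, 1.0)
    if (n_channels > 1L)
      channel[pos] <- sample.int(n_channels, n_emitters, replace = TRUE)
  }
  emitter_volume(intensity, channel, n_channels)
}

#' Save a design (or trained design) to a directory
#'
#' Writes `design.json` (geometry, material, `t_max`, latents, seeds, package
#' version) plus one 32-bit TIFF thickness map per surface
#' (`thickness_k.tif`, normalized by `t_max`; samples are quantized to the
#' 32-bit integer range by the TIFF writer) and, for trained designs, the
#' loss trace as `trace.csv`. All floating-point design state in the JSON is
#' serialized at 17 significant digits, which round-trips IEEE doubles
#' exactly, so a reloaded design replays training bit-identically.
#'
#' @param design A [diffractive_design] or `trained_design`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_design <- function(design, dir) {
  trained <- inherits(design, "trained_design")
  trace <- if (trained) design$trace else NULL
  cfg <- if (trained) design$config else NULL
  if (trained) design <- design$design
  stopifnot(inherits(design, "diffractive_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- design$geometry
  mat <- design$material
  spec <- list(
    package_version = as.character(utils::packageVersion("diffpsf")),
    geometry = list(K = geom$K, M = geom$M,
                    wavelengths = num17(geom$wavelengths),
                    pitch = num17(geom$pitch), d = num17(geom$d),
                    d_i = num17(geom$d_i), d_o = num17(geom$d_o),
                    d_pp = num17(geom$d_pp),
                    input_shape = geom$input_shape,
                    output_shape = geom$output_shape,
                    medium_extent = geom$medium_extent,
                    aperture = geom$aperture,
                    medium = if (is.null(geom$medium)) NULL else
                      list(wavelength = num17(geom$medium$wavelength),
                           index = num17(geom$medium$index))),
    material = if (inherits(mat, "dispersion"))
      list(wavelength = num17(mat$wavelength), index = num17(mat$index))
      else num17(mat),
    t_max = num17(design$t_max), seed = design$seed,
    vectorization = "plane-major, then row-major within plane",
    latents = lapply(design$latents, function(l) num17(as.vector(l))),
    train_config = if (is.null(cfg)) NULL else
      list(iterations = cfg$iterations, lr = cfg$lr,
           lr_schedule = cfg$lr_schedule, seed = cfg$seed,
           b_train = format(cfg$policy$b_train),
           b_test = format(cfg$policy$b_test))
  )
  jsonlite::write_json(spec, file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (k in seq_along(design$latents)) {
    t_s <- thickness_from_latent(design$latents[[k]], design$t_max)
    tiff::writeTIFF(t_s / max(design$t_max, 1e-300),
                    file.path(dir, sprintf("thickness_%d.tif", k)),
                    bits.per.sample = 32L)
  }
  if (!is.null(trace))
    utils::write.csv(trace, file.path(dir, "trace.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a design saved by [save_design()]
#'
#' @param dir Directory written by [save_design()].
#' @return A [diffractive_design].
#' @export
load_design <- function(dir) {
  path <- file.path(dir, "design.json")
  if (!file.exists(path)) stop("no design.json in ", dir)
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- spec$geometry
  medium <- if (!is.null(g$medium))
    dispersion(as.numeric(g$medium$wavelength), as.numeric(g$medium$index))
    else NULL
  geom <- processor_geometry(K = g$K, M = g$M,
                             wavelengths = as.numeric(g$wavelengths),
                             input_shape = g$input_shape,
                             output_shape = g$output_shape,
                             pitch = as.numeric(g$pitch), d = as.numeric(g$d),
                             d_i = as.numeric(g$d_i), d_o = as.numeric(g$d_o),
                             d_pp = as.numeric(g$d_pp), medium = medium,
                             medium_extent = g$medium_extent,
                             aperture = g$aperture)
  material <- if (is.list(spec$material))
    dispersion(as.numeric(spec$material$wavelength),
               as.numeric(spec$material$index))
    else as.numeric(spec$material)
  lat_raw <- spec$latents
  if (is.matrix(lat_raw)) lat_raw <- lapply(seq_len(nrow(lat_raw)),
                                            function(k) lat_raw[k, ])
  latents <- lapply(lat_raw, function(v) matrix(as.numeric(v), g$M, g$M))
  diffractive_design(geom, material = material, latents = latents,
                     t_max = as.numeric(spec$t_max), seed = spec$seed %||% 1L)
}

#' Save a transformation matrix with metadata
#'
#' CSV payload plus a JSON sidecar recording the shape, role and the
#' vectorization convention.
#'
#' @param A Matrix to save.
#' @param path CSV path (a `.json` sidecar is written next to it).
#' @param role Role tag, e.g. `"target"`, `"realized"`, `"scaled"`.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(A, path, role = "target") {
  utils::write.table(A, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(n_out = nrow(A), n_in = ncol(A), role = role,
                            vectorization = "plane-major, then row-major within plane"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a matrix saved by [save_matrix()]
#'
#' @param path CSV path.
#' @return The matrix (metadata, if present, attached as attribute `meta`).
#' @export
load_matrix <- function(path) {
  A <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(A) <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side))
    attr(A, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  A
}

#' Write a run manifest
#'
#' JSON record of a run: config echo, seeds, package version, timings and
#' final metrics — enough to re-execute the run bit-identically on a single
#' thread.
#'
#' @param path Output JSON path.
#' @param config Arbitrary config list to echo.
#' @param seeds Named list/vector of seeds.
#' @param metrics Named list of final metrics.
#' @param timings Named list of per-stage timings (seconds).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds, metrics = list(),
                           timings = list()) {
  jsonlite::write_json(
    list(package = "diffpsf",
         version = as.character(utils::packageVersion("diffpsf")),
         r_version = R.version.string,
         config = config, seeds = seeds, metrics = metrics,
         timings = timings),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
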