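#' Render a synthetic double-frame particle image pair
#'
#' Projects two particle ensembles (the same tracers at the two laser
#' pulses, `dt` apart) through a virtual camera and renders each particle
#' as a 2D Gaussian spot at its mapped sensor position. Optional constant
#' background and noise (Gaussian read noise plus shot-like noise scaling
#' with the square root of the local signal) are controlled by
#' `noise_level` and are reproducible from `seed`.
#'
#' Intensities are kept on a [0, 1] scale (1 = sensor full well); use
#' [write_image_pair()] to store 16-bit TIFF frames.
#'
#' @param particles_t0,particles_t1 `aneupiv_particles` at the two pulses
#'   (same seed lineage).
#' @param camera An `aneupiv_camera`.
#' @param dt_us Interframe time (us).
#' @param noise_level Noise amplitude relative to the particle peak
#'   intensity (0 = noiseless).
#' @param background Constant background level.
#' @param amplitude Particle peak intensity.
#' @param seed Seed for the noise realization.
#' @param phase,cycle Acquisition indices stored with the pair.
#' @return Object of class `aneupiv_image_pair` with `frame_a`, `frame_b`
#'   (matrices, row = v, column = u), `dt_us`, `camera_id`, `phase`,
#'   `cycle`.
#' @export
render_image_pair <- function(particles_t0, particles_t1, camera,
                              dt_us, noise_level = 0, background = 0.05,
                              amplitude = 0.8, seed = 1L,
                              phase = 1L, cycle = 1L) {
  stopifnot(inherits(particles_t0, "aneupiv_particles"),
            inherits(particles_t1, "aneupiv_particles"),
            inherits(camera, "aneupiv_camera"))
  if (dt_us <= 0) stop("interframe time must be positive")
  if (particles_t0$seed != particles_t1$seed)
    stop("frame ensembles must share the same seed lineage")
  render_one <- function(p, noise_seed) {
    uv <- world_to_sensor(camera, p$pos)
    n <- nrow(uv)
    sig <- rep(p$diameter_px / 4, n)
    img <- cpp_render_spots(uv[, 1], uv[, 2], rep(amplitude, n), sig,
                            camera$sensor[2], camera$sensor[1],
                            radius = max(3 * sig[1], 3))
    img <- img + background
    if (noise_level > 0) {
      img <- img + with_seed(noise_seed, {
        nr <- length(img)
        matrix(rnorm(nr, sd = noise_level * amplitude) +
                 rnorm(nr, sd = noise_level *
                         sqrt(pmax(img, 0) * amplitude)),
               nrow(img), ncol(img))
      })
      img[img < 0] <- 0
    }
    img
  }
  structure(list(
    frame_a = render_one(particles_t0, derive_seed(seed, 1L)),
    frame_b = render_one(particles_t1, derive_seed(seed, 2L)),
    dt_us = dt_us, camera_id = camera$camera_id,
    phase = phase, cycle = cycle), class = "aneupiv_image_pair")
}

#' Write / read an image pair as 16-bit TIFF
#'
#' Frames are stored as 16-bit grayscale TIFF named
#' `{scenario}_{cycle:03d}_{phase:04d}_{cam}{frame}.tif`.
#'
#' @param pair An `aneupiv_image_pair`.
#' @param dir Output directory.
#' @param scenario Scenario label used in the filename.
#' @return Invisibly, the two file paths.
#' @export
write_image_pair <- function(pair, dir, scenario = "noFD") {
  stopifnot(inherits(pair, "aneupiv_image_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- sprintf("%s_%03d_%04d_%s", scenario, pair$cycle, pair$phase,
                  pair$camera_id)
  fa <- file.path(dir, paste0(base, "a.tif"))
  fb <- file.path(dir, paste0(base, "b.tif"))
  clamp <- function(x) pmin(pmax(x, 0), 1)
  tiff::writeTIFF(clamp(pair$frame_a), fa, bits.per.sample = 16)
  tiff::writeTIFF(clamp(pair$frame_b), fb, bits.per.sample = 16)
  invisible(c(fa, fb))
}

#' @rdname write_image_pair
#' @param file_a,file_b Paths of the two frames.
#' @param dt_us,phase,cycle,camera_id Acquisition metadata to attach.
#' @export
read_image_pair <- function(file_a, file_b, dt_us, phase = 1L, cycle = 1L,
                            camera_id = "cam1") {
  structure(list(frame_a = tiff::readTIFF(file_a),
                 frame_b = tiff::readTIFF(file_b),
                 dt_us = dt_us, camera_id = camera_id,
                 phase = phase, cycle = cycle),
            class = "aneupiv_image_pair")
}
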