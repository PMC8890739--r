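#' Seed tracer particles in the illuminated slab
#'
#' Draws a reproducible uniform random ensemble of ideal tracer particles
#' inside the lumen, within the thin illuminated slab around the sagittal
#' plane. Tracers are ideal (particle inertia and slip are neglected; the
#' physical 10 um tracers have Stokes numbers far below one).
#'
#' @param model An `aneupiv_flow_model` (supplies geometry and slab
#'   thickness).
#' @param density Seeding density (particles per mm^2 of lumen area).
#' @param diameter_px Rendered particle-image diameter (px, e^-2 intensity
#'   diameter); at least 2 px to avoid peak locking.
#' @param seed RNG seed; the ensemble is reproducible from it.
#' @return Object of class `aneupiv_particles`: `pos` (n x 3 matrix, mm),
#'   `diameter_px`, `seed`.
#' @export
particle_ensemble <- function(model, density = 10, diameter_px = 3,
                              seed = 1L) {
  stopifnot(inherits(model, "aneupiv_flow_model"))
  if (diameter_px < 2) stop("particle image diameter must be >= 2 px")
  geom <- model$geometry
  area <- sum(geom$lumen_mask) * geom$config$pitch^2   # mm^2
  n <- max(1L, as.integer(round(density * area)))
  ex <- geom$config$extent_x; ey <- geom$config$extent_y
  pos <- with_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    filled <- 0L
    while (filled < n) {
      m <- (n - filled) * 2L + 16L
      x <- runif(m, ex[1], ex[2])
      y <- runif(m, ey[1], ey[2])
      keep <- which(in_lumen(geom, x, y))
      take <- seq_len(min(length(keep), n - filled))
      idx <- keep[take]
      if (length(idx)) {
        rows <- filled + seq_along(idx)
        out[rows, 1] <- x[idx]
        out[rows, 2] <- y[idx]
        filled <- filled + length(idx)
      }
    }
    out[, 3] <- runif(n, -model$slab_half, model$slab_half)
    out
  })
  structure(list(pos = pos, diameter_px = diameter_px, seed = as.integer(seed)),
            class = "aneupiv_particles")
}

#' Advect tracer particles through the flow map
#'
#' Fourth-order Runge-Kutta integration of particle positions through the
#' velocity field. Particles that leave the lumen are respawned at the
#' inlet (preserving the particle count, deterministically from the
#' ensemble seed).
#'
#' @param particles An `aneupiv_particles` ensemble.
#' @param model An `aneupiv_flow_model`, or a function
#'   `(points, t) -> n x 3` velocity matrix (m/s) for testing kinematics.
#' @param t Start time (s).
#' @param dt Advection duration (s).
#' @param n_steps Number of RK4 substeps.
#' @param cycle Cycle index forwarded to the model.
#' @param respawn Respawn particles that leave the lumen (disable for pure
#'   kinematics tests).
#' @return The advected ensemble.
#' @export
advect_particles <- function(particles, model, t, dt, n_steps = 1L,
                             cycle = 1L, respawn = TRUE) {
  stopifnot(inherits(particles, "aneupiv_particles"))
  vel <- if (is.function(model)) {
    function(p, tt) model(p, tt)
  } else {
    function(p, tt) sample_velocity(model, p, tt, cycle)
  }
  pos <- particles$pos
  h <- dt / n_steps
  mm_per_s <- 1000  # velocities in m/s, positions in mm
  for (k in seq_len(n_steps)) {
    tk <- t + (k - 1) * h
    k1 <- vel(pos, tk) * mm_per_s
    if (!all(is.finite(k1))) stop("non-finite velocities during advection")
    k2 <- vel(pos + 0.5 * h * k1, tk + 0.5 * h) * mm_per_s
    k3 <- vel(pos + 0.5 * h * k2, tk + 0.5 * h) * mm_per_s
    k4 <- vel(pos + h * k3, tk + h) * mm_per_s
    pos <- pos + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (respawn && !is.function(model)) {
    geom <- model$geometry
    out <- which(!in_lumen(geom, pos[, 1], pos[, 2]) |
                   abs(pos[, 3]) > model$slab_half)
    if (length(out)) {
      R_v <- geom$vessel_halfwidth
      repl <- with_seed(derive_seed(particles$seed, 7L, length(out)), {
        cbind(geom$config$extent_x[1] +
                runif(length(out), 0, 0.5),
              runif(length(out), -R_v * 0.98, R_v * 0.98),
              runif(length(out), -model$slab_half, model$slab_half))
      })
      pos[out, ] <- repl
    }
  }
  particles$pos <- pos
  particles
}
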