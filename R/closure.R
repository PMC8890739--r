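#' Window-filtered ground-truth reference for PIV closure
#'
#' The reference a PIV measurement should be compared against is the true
#' tracer displacement averaged over each interrogation window (the
#' window's top-hat spatial response), not the pointwise field: a
#' correlation-based estimator reports the mean particle displacement
#' inside the window. This helper evaluates that reference on the vector
#' grid: in-plane components from the advected tracer displacement over
#' the interframe time (secant displacement, as PIV measures), the
#' out-of-plane component from the model's w field, both averaged over a
#' sub-sampled window stencil restricted to the lumen (where tracers
#' exist).
#'
#' @param model An `aneupiv_flow_model`.
#' @param x,y Vector-grid world coordinates (mm).
#' @param t0 Recording time (s).
#' @param cycle Cycle index.
#' @param dt_us Interframe time (us).
#' @param magnification Magnification (um/px).
#' @param view_angle Stereo half-angle (degrees); widens the window
#'   footprint in x by 1/cos(theta).
#' @param window Final interrogation window (px).
#' @param sub Stencil spacing (px).
#' @return List of matrices `u`, `v`, `w` (m/s) on the vector grid.
#' @export
filtered_truth_field <- function(model, x, y, t0, cycle, dt_us,
                                 magnification, view_angle = 35,
                                 window = 32L, sub = 4L) {
  st <- .closure_stencil(model, x, y, magnification, view_angle, window,
                         sub)
  ip <- .filtered_inplane(model, st, t0, dt_us)
  list(u = ip$u, v = ip$v, w = .filtered_w(model, st, t0, cycle))
}

# sub-sampled window stencil around every vector location
.closure_stencil <- function(model, x, y, magnification, view_angle,
                             window, sub) {
  geom <- model$geometry
  m_mm <- magnification / 1000
  th <- view_angle * pi / 180
  offs_px <- seq(-window / 2 + sub / 2, window / 2 - sub / 2, by = sub)
  ox <- offs_px * m_mm / cos(th)
  oy <- offs_px * m_mm
  nx <- length(x); ny <- length(y); nv <- nx * ny
  gx <- rep(x, each = ny); gy <- rep(y, nx)
  ns <- length(ox)^2
  OX <- rep(rep(ox, each = length(oy)), times = nv)
  OY <- rep(rep(oy, times = length(ox)), times = nv)
  PX <- rep(gx, each = ns) + OX
  PY <- rep(gy, each = ns) + OY
  inside <- in_lumen(geom, PX, PY)
  grp <- rep(seq_len(nv), each = ns)
  avg <- function(v) {
    v[!inside] <- NA
    sm <- rowsum(ifelse(is.na(v), 0, v), grp)
    n <- rowsum(as.numeric(!is.na(v)), grp)
    out <- as.vector(sm / pmax(n, 1))
    out[n == 0] <- NA
    matrix(out, ny, nx)
  }
  list(pts = cbind(PX, PY, 0), avg = avg)
}

# window-averaged in-plane secant velocity (cycle-independent: the
# in-plane field does not vary between cycles)
.filtered_inplane <- function(model, st, t0, dt_us) {
  pe <- structure(list(pos = st$pts, diameter_px = 3, seed = 1L),
                  class = "aneupiv_particles")
  pe1 <- advect_particles(pe, model, t0, dt_us * 1e-6, n_steps = 2L,
                          cycle = 1L, respawn = FALSE)
  disp <- (pe1$pos - st$pts) / dt_us * 1000
  list(u = st$avg(disp[, 1]), v = st$avg(disp[, 2]))
}

# window-averaged out-of-plane velocity for one cycle realization
.filtered_w <- function(model, st, t0, cycle) {
  st$avg(sample_velocity(model, st$pts, t0, cycle)[, 3])
}

#' End-to-end PIV closure error
#'
#' Runs (or reuses) a full synthetic measurement of one scenario and
#' compares the phase-averaged reconstructed field against the
#' window-filtered ground truth of the same realizations, reporting the
#' root-mean-square error over the sac ROI in pixel-equivalent units
#' (velocity error times interframe time over magnification). The
#' pointwise-truth RMS (no window filtering) is reported alongside.
#'
#' @param cfg An `aneupiv_run_config`.
#' @param meas Optional result of [measure_scenario()] under `cfg` to
#'   reuse.
#' @param progress Emit progress messages.
#' @return List: `rms_px` (3-component, vs filtered truth), `rms_px_raw`
#'   (vs pointwise truth), `components` (per-component RMS vs filtered
#'   truth), `dt_us`, and the measurement `meas`.
#' @export
piv_closure <- function(cfg, meas = NULL, progress = FALSE) {
  if (is.null(meas)) meas <- measure_scenario(cfg, progress = progress)
  model <- meas$model; pac <- meas$pac
  dt_us <- meas$dt_us
  mag <- cfg$camera$magnification
  Tdur <- model$waveform$cycle_duration
  M <- pac$n_phases; N <- pac$n_cycles
  roi <- roi_mask_for(meas$geom, pac$x, pac$y)
  ny <- length(pac$y); nx <- length(pac$x)

  pts <- cbind(rep(pac$x, each = ny), rep(pac$y, nx))
  st <- .closure_stencil(model, pac$x, pac$y, mag,
                         cfg$camera$view_angle,
                         cfg$piv$windows[length(cfg$piv$windows)], 4L)
  err2 <- matrix(0, ny, nx); err2_raw <- matrix(0, ny, nx)
  comp2 <- c(u = 0, v = 0, w = 0)
  for (p in seq_len(M)) {
    t0 <- (p - 1) * Tdur / M
    ip <- .filtered_inplane(model, st, t0, dt_us)
    tu <- ip$u; tv <- ip$v
    tw <- matrix(0, ny, nx)
    raw <- matrix(0, ny, nx * 3)
    for (ic in seq_len(N)) {
      tw <- tw + .filtered_w(model, st, t0, ic) / N
      raw <- raw + matrix(sample_velocity(model, pts, t0, ic), ny) / N
    }
    eu <- pac$mean[, , 1, p] - tu
    ev <- pac$mean[, , 2, p] - tv
    ew <- pac$mean[, , 3, p] - tw
    err2 <- err2 + (eu^2 + ev^2 + ew^2) / M
    comp2 <- comp2 + c(mean(eu[roi]^2, na.rm = TRUE),
                       mean(ev[roi]^2, na.rm = TRUE),
                       mean(ew[roi]^2, na.rm = TRUE)) / M
    ru <- pac$mean[, , 1, p] - raw[, seq_len(nx)]
    rv <- pac$mean[, , 2, p] - raw[, nx + seq_len(nx)]
    rw <- pac$mean[, , 3, p] - raw[, 2 * nx + seq_len(nx)]
    err2_raw <- err2_raw + (ru^2 + rv^2 + rw^2) / M
    if (progress && p %% 16 == 0)
      message(sprintf("  closure reference: phase %d/%d", p, M))
  }
  px <- dt_us / mag    # m/s -> px-equivalent
  list(rms_px = sqrt(mean(err2[roi], na.rm = TRUE)) * px,
       rms_px_raw = sqrt(mean(err2_raw[roi], na.rm = TRUE)) * px,
       components = sqrt(comp2) * px,
       dt_us = dt_us, meas = meas)
}
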