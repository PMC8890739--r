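#' Analytical pulsatile aneurysm flow model
#'
#' Closed-form time-dependent 3-component velocity field on the sagittal
#' plane of the idealized side-wall aneurysm. The parent vessel carries a
#' Poiseuille profile modulated by the pulsatile waveform. Inside the sac,
#' the in-plane field is the sum of
#' \itemize{
#'   \item a clockwise ring vortex (tangential profile
#'     `~ s^3 (1-s)`, `s = r/R_sac`) whose speed peaks in a near-wall
#'     alignment band and vanishes at the sac center and at the wall, and
#'   \item an inflow jet entering at the distal ostium, modeled through a
#'     stream function (Gaussian cross-profile of width `jet_width`,
#'     multiplied by a smoothstep wall envelope), so the in-plane sac field
#'     is analytically divergence-free, satisfies no-slip exactly at the
#'     wall, and closes the jet flux along the walls.
#' }
#' This reproduces the observed topology of the untreated aneurysm: a jet
#' entering at the distal neck and impinging on the opposite wall, flow
#' aligned along the lumen, and a central stagnation zone.
#'
#' Every velocity scales with the waveform, so the whole field is periodic
#' in time with the cycle duration. A treatment scenario (see
#' [scenario_config()]) attenuates the in-sac in-plane field, shifts the jet
#' entry, and adds a zero-mean stochastic out-of-plane component that is
#' piecewise constant over acquisition phase bins and reproducible from the
#' model seed.
#'
#' @param geometry An [build_geometry()] result.
#' @param fluid An [fluid_properties()].
#' @param waveform An [waveform_config()]; default derives the peak velocity
#'   from the Reynolds target using `fluid` and the vessel diameter.
#' @param jet_width Gaussian half-width of the inflow jet (mm).
#' @param jet_strength Peak jet speed as a fraction of the parent-vessel
#'   peak centerline velocity.
#' @param jet_return_factor Width of the confining window of the jet
#'   stream function, as a multiple of `jet_width`; the jet's return flow
#'   stays within this lateral distance of the axis.
#' @param vortex_strength Peak tangential vortex speed, same normalization.
#' @param wall_band Thickness of the wall envelope as a fraction of the sac
#'   radius.
#' @param slab_half Half-thickness of the illuminated slab (mm).
#' @param oop_corr_length Spatial correlation length of the stochastic
#'   out-of-plane disturbance (mm).
#' @param oop_modes Number of random cosine modes of the disturbance
#'   field; more modes bring the per-bin realized variance closer to its
#'   Gaussian-field expectation.
#' @param n_phases Number of acquisition phase bins per cycle over which the
#'   stochastic out-of-plane component is piecewise constant.
#' @param seed Root seed for all stochastic model components.
#' @param scenario Optional [scenario_config()]; usually applied later via
#'   [apply_scenario()].
#' @return Object of class `aneupiv_flow_model`.
#' @export
aneurysm_flow_model <- function(geometry = build_geometry(),
                                fluid = fluid_properties(),
                                waveform = NULL,
                                jet_width = 1.5, jet_strength = 0.30,
                                jet_return_factor = 3,
                                vortex_strength = 0.15, wall_band = 0.30,
                                slab_half = 0.25, oop_corr_length = 3,
                                oop_modes = 256L,
                                n_phases = 1000, seed = 1L,
                                scenario = NULL) {
  if (is.null(waveform)) {
    waveform <- waveform_config(
      fluid = fluid, vessel_diameter = geometry$config$vessel_diameter)
  }
  model <- list(geometry = geometry, fluid = fluid, waveform = waveform,
                jet_width = jet_width, jet_strength = jet_strength,
                jet_return_factor = jet_return_factor,
                vortex_strength = vortex_strength, wall_band = wall_band,
                slab_half = slab_half, oop_corr_length = oop_corr_length,
                oop_modes = as.integer(oop_modes),
                n_phases = as.integer(n_phases), seed = as.integer(seed),
                scenario = NULL)
  class(model) <- "aneupiv_flow_model"
  if (!is.null(scenario)) model <- apply_scenario(model, scenario)
  model
}

#' Apply a treatment scenario to a flow model
#'
#' @param model An `aneupiv_flow_model` without a scenario.
#' @param scenario An [scenario_config()].
#' @return The model with the scenario applied.
#' @export
apply_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "aneupiv_flow_model"),
            inherits(scenario, "aneupiv_scenario"))
  if (!is.null(model$scenario))
    stop("model already has a scenario applied; start from the base model")
  model$scenario <- scenario
  model
}

#' @export
print.aneupiv_flow_model <- function(x, ...) {
  cat("Analytical aneurysm flow model\n")
  cat(sprintf("  U_peak = %.4g m/s (Re = %.0f, Wo = %.3g), T = %g s\n",
              x$waveform$peak_velocity, x$waveform$reynolds,
              x$waveform$womersley, x$waveform$cycle_duration))
  cat(sprintf("  jet %.2f U_peak (width %g mm), vortex %.2f U_peak\n",
              x$jet_strength, x$jet_width, x$vortex_strength))
  if (is.null(x$scenario)) cat("  scenario: none (base model)\n")
  else print(x$scenario)
  invisible(x)
}

# C2 smootherstep wall envelope W(s) and derivative dW/ds; s = r / R_sac.
# C2 continuity keeps the finite-difference divergence of the stream
# function field clean across the band edges.
.wall_envelope <- function(s, band) {
  u <- pmin(pmax((1 - s) / band, 0), 1)
  list(W = u^3 * (6 * u^2 - 15 * u + 10),
       dW = -(30 * u^2 * (u - 1)^2) / band)
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# jet entry point and unit direction, including any scenario shift
.jet_axis <- function(model) {
  geom <- model$geometry
  shift <- if (is.null(model$scenario)) 0 else model$scenario$jet_entry_shift
  entry <- geom$jet_entry + c(shift, 0)
  d <- geom$jet_target - entry
  list(entry = entry, dir = d / sqrt(sum(d^2)))
}

# In-plane velocity (n x 2, m/s) of the sac field for points given by
# offsets from the sac center, at unit waveform amplitude and unit
# attenuation. Shared by sample_velocity and local_mean_speed.
.sac_inplane_unit <- function(model, dx, dy) {
  geom <- model$geometry
  R_s <- geom$sac_radius
  U_p <- model$waveform$peak_velocity
  r <- sqrt(dx^2 + dy^2)
  s <- r / R_s
  env <- .wall_envelope(s, model$wall_band)
  # tangential unit vector (counter-clockwise); zero at the exact center
  r_safe <- ifelse(r > 0, r, 1)
  tx <- -dy / r_safe
  ty <- dx / r_safe

  # ring vortex circulates clockwise (entry at the distal neck, over the
  # dome, back along the proximal wall), the alignment the inflow jet
  # imposes at its impingement point
  V <- model$vortex_strength * U_p
  g <- (256 / 27) * s^3 * (1 - s)
  g[s > 1] <- 0
  ux <- -V * g * tx
  uy <- -V * g * ty

  # Jet stream function: erf cross-profile windowed by a wide Gaussian
  # (width jet_return_factor * jet_width), so the jet carries no net flux
  # at large lateral distance and its return flow stays confined to the
  # flanks instead of circling the whole wall; velocities follow from the
  # product rule, keeping the field exactly divergence-free.
  jet <- .jet_axis(model)
  Uj <- model$jet_strength * U_p
  px <- dx + geom$sac_center[1] - jet$entry[1]
  py <- dy + geom$sac_center[2] - jet$entry[2]
  nx <- -jet$dir[2]; ny <- jet$dir[1]
  xi <- px * nx + py * ny
  sigma <- model$jet_width
  sig_o <- model$jet_return_factor * sigma
  env_o <- exp(-xi^2 / (2 * sig_o^2))
  core <- exp(-xi^2 / (2 * sigma^2))
  phi_erf <- sigma * sqrt(pi / 2) * .erf(xi / (sigma * sqrt(2)))
  dphi <- core * env_o + phi_erf * (-xi / sig_o^2) * env_o
  phi <- phi_erf * env_o
  ux <- ux + Uj * (env$W * dphi * jet$dir[1] - phi * env$dW / R_s * tx)
  uy <- uy + Uj * (env$W * dphi * jet$dir[2] - phi * env$dW / R_s * ty)

  # Stagnation correction: the jet's far tail leaves a small residual
  # velocity at the sac centroid. Subtract a wall-windowed uniform
  # counterflow (stream function W(s) * psi_linear) that cancels it
  # exactly at the center; the construction stays divergence-free and
  # no-slip, and its magnitude (a few percent of the jet speed) barely
  # perturbs the rest of the field.
  xi_c <- (geom$sac_center[1] - jet$entry[1]) * nx +
    (geom$sac_center[2] - jet$entry[2]) * ny
  env_oc <- exp(-xi_c^2 / (2 * sig_o^2))
  dphi_c <- exp(-xi_c^2 / (2 * sigma^2)) * env_oc +
    sigma * sqrt(pi / 2) * .erf(xi_c / (sigma * sqrt(2))) *
    (-xi_c / sig_o^2) * env_oc
  ulx <- Uj * dphi_c * jet$dir[1]
  uly <- Uj * dphi_c * jet$dir[2]
  sig_c <- 0.3 * R_s
  G <- exp(-r^2 / (2 * sig_c^2))
  psi_lin <- -ulx * dy + uly * dx
  ux <- ux + env$W * (-G * ulx + psi_lin * G * r / sig_c^2 * tx) -
    G * psi_lin * env$dW / R_s * tx
  uy <- uy + env$W * (-G * uly + psi_lin * G * r / sig_c^2 * ty) -
    G * psi_lin * env$dW / R_s * ty
  # clamp envelope outside the sac
  out <- s >= 1
  ux[out] <- 0; uy[out] <- 0
  cbind(ux, uy)
}

# Smooth unit-variance random field for the stochastic out-of-plane
# disturbance of one (cycle, phase bin): a sum of K random cosine modes
# whose wavevector magnitudes are Rayleigh-distributed with scale
# 1/corr_length, giving the isotropic Gaussian correlation function
# exp(-d^2 / (2 l^2)) (monotonically decaying, as a correlation length
# should imply; a single fixed |k| would give an oscillatory J0
# covariance instead).
.oop_eps <- function(model, x, y, cycle, phase_bin) {
  K <- model$oop_modes %||% 256L
  # the normalized disturbance pattern is drawn per (cycle, phase bin)
  # only -- deliberately NOT per scenario: treatment arms share common
  # random numbers, so between-scenario comparisons are paired and free
  # of between-arm realization noise (the scenario controls the
  # amplitude sigma_z, not the pattern)
  seed <- derive_seed(model$seed, 17L, cycle, phase_bin)
  modes <- with_seed(seed, {
    list(beta = runif(K, 0, 2 * pi), phase = runif(K, 0, 2 * pi),
         kmag = sqrt(-2 * log(runif(K))) / model$oop_corr_length)
  })
  eps <- 0
  for (i in seq_len(K)) {
    eps <- eps + cos(modes$kmag[i] *
                       (cos(modes$beta[i]) * x + sin(modes$beta[i]) * y) +
                       modes$phase[i])
  }
  eps * sqrt(2 / K)
}

#' Sample the model velocity field
#'
#' Evaluates the 3-component velocity (m/s) at arbitrary points and time.
#' Deterministic for fixed model, points, time and cycle; periodic in `t`
#' with the cycle duration. Points outside the modeled lumen or outside the
#' illuminated slab return zero velocity and are flagged in the `outside`
#' attribute rather than raising an error.
#'
#' @param model An `aneupiv_flow_model`.
#' @param points Numeric matrix `n x 2` (x, y) or `n x 3` (x, y, z), mm.
#' @param t Time (s).
#' @param cycle Cycle index (integer >= 1); selects the realization of the
#'   stochastic out-of-plane component.
#' @return `n x 3` matrix of (u, v, w) in m/s with logical attribute
#'   `outside`.
#' @export
sample_velocity <- function(model, points, t, cycle = 1L) {
  stopifnot(inherits(model, "aneupiv_flow_model"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (!all(is.finite(points))) stop("points must be finite")
  x <- points[, 1]; y <- points[, 2]
  z <- if (ncol(points) >= 3) points[, 3] else rep(0, length(x))

  geom <- model$geometry
  R_v <- geom$vessel_halfwidth
  R_s <- geom$sac_radius
  C <- geom$sac_center
  scen <- model$scenario
  alpha <- if (is.null(scen)) 0 else scen$alpha
  damp <- if (is.null(scen)) 0 else scen$peak_damping

  wf <- model$waveform
  wt <- waveform_eval(wf, t)
  wt_sac <- waveform_eval(wf, t, peak_damping = damp)

  dx <- x - C[1]; dy <- y - C[2]
  in_sac <- (dx^2 + dy^2) <= R_s^2 & y > R_v
  in_vessel <- abs(y) <= R_v
  in_slab <- abs(z) <= model$slab_half
  outside <- !((in_sac | in_vessel) & in_slab)

  n <- length(x)
  vel <- matrix(0, n, 3)

  iv <- which(in_vessel & in_slab)
  if (length(iv)) {
    vel[iv, 1] <- wf$peak_velocity * wt * (1 - (y[iv] / R_v)^2)
  }

  is <- which(in_sac & in_slab & !in_vessel)
  if (length(is)) {
    uv <- .sac_inplane_unit(model, dx[is], dy[is])
    fac <- wt_sac * (1 - alpha)
    vel[is, 1] <- uv[, 1] * fac
    vel[is, 2] <- uv[, 2] * fac
    if (!is.null(scen) && scen$oop_fluctuation > 0) {
      ubar <- sqrt(uv[, 1]^2 + uv[, 2]^2) * wf$mean_rel * (1 - alpha)
      pb <- floor(((t / wf$cycle_duration) %% 1) * model$n_phases)
      eps <- .oop_eps(model, x[is], y[is], as.integer(cycle), as.integer(pb))
      vel[is, 3] <- scen$oop_fluctuation * ubar * eps
    }
  }
  attr(vel, "outside") <- outside
  vel
}

#' Local cycle-mean speed of the in-plane field
#'
#' Closed-form time average over one cycle of the in-plane speed at the
#' given points (every component scales with the waveform, so the cycle
#' mean is the instantaneous spatial pattern times the waveform cycle
#' mean). Includes scenario attenuation; zero outside the lumen.
#'
#' @inheritParams sample_velocity
#' @return Numeric vector of cycle-mean speeds (m/s).
#' @export
local_mean_speed <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  x <- points[, 1]; y <- points[, 2]
  geom <- model$geometry
  C <- geom$sac_center
  R_v <- geom$vessel_halfwidth
  R_s <- geom$sac_radius
  scen <- model$scenario
  alpha <- if (is.null(scen)) 0 else scen$alpha
  wf <- model$waveform
  out <- numeric(length(x))
  dx <- x - C[1]; dy <- y - C[2]
  in_sac <- (dx^2 + dy^2) <= R_s^2 & y > R_v
  in_vessel <- abs(y) <= R_v
  iv <- which(in_vessel)
  if (length(iv)) {
    out[iv] <- wf$peak_velocity * wf$mean_rel * (1 - (y[iv] / R_v)^2)
  }
  is <- which(in_sac & !in_vessel)
  if (length(is)) {
    uv <- .sac_inplane_unit(model, dx[is], dy[is])
    out[is] <- sqrt(uv[, 1]^2 + uv[, 2]^2) * wf$mean_rel * (1 - alpha)
  }
  out
}

#' Evaluate the model on the geometry grid
#'
#' Ground-truth evaluation of the full velocity field on the cell-centered
#' geometry grid; points outside the lumen are zero.
#'
#' @inheritParams sample_velocity
#' @return Array `ny x nx x 3` (m/s).
#' @export
sample_velocity_grid <- function(model, t, cycle = 1L) {
  geom <- model$geometry
  nx <- length(geom$x); ny <- length(geom$y)
  pts <- cbind(rep(geom$x, each = ny), rep(geom$y, nx))
  v <- sample_velocity(model, pts, t, cycle)
  array(v, dim = c(ny, nx, 3))
}
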