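#' Pulsatile inflow waveform
#'
#' Parametric cardiac waveform with one systolic peak per cycle: a constant
#' base level plus two periodic Gaussian bumps (systolic peak and a smaller
#' diastolic bump), normalized so the cycle maximum is exactly 1. The
#' centerline velocity at time t is `peak_velocity * waveform_eval(wf, t)`.
#'
#' If `peak_velocity` is `NULL` it is derived from the target peak Reynolds
#' number: `U_peak = Re * nu / D`. The Womersley number implied by the
#' chosen cycle duration is stored alongside; period and magnification are
#' not fixed by the study conditions, so the waveform satisfies the
#' Reynolds target exactly and reports the implied Womersley number.
#'
#' The default base level is calibrated once so that the cycle mean of the
#' normalized waveform is 0.778, the cyclic-mean to cyclic-max ratio shown
#' by the untreated sac statistics.
#'
#' @param cycle_duration Cycle duration T (s).
#' @param peak_velocity Peak centerline velocity (m/s) or `NULL` to derive
#'   from `reynolds`.
#' @param reynolds Target peak Reynolds number.
#' @param base_level Constant base component (arbitrary units before
#'   normalization).
#' @param systolic_amp,systolic_peak_phase,systolic_width Amplitude, phase
#'   (fraction of cycle) and width (fraction of cycle) of the systolic peak.
#' @param diastolic_amp,diastolic_phase,diastolic_width Same for the
#'   diastolic bump.
#' @param fluid An [fluid_properties()] object.
#' @param vessel_diameter Vessel diameter (mm) used for Re and Wo.
#' @return Object of class `aneupiv_waveform` with the shape parameters and
#'   derived `peak_velocity`, `reynolds`, `womersley`, `mean_rel` (cycle
#'   mean of the normalized waveform) and `peak_phase` (fraction of cycle).
#' @export
waveform_config <- function(cycle_duration = 1.0, peak_velocity = NULL,
                            reynolds = 1025, base_level = 2.29,
                            systolic_amp = 1.0, systolic_peak_phase = 0.20,
                            systolic_width = 0.07,
                            diastolic_amp = 0.35, diastolic_phase = 0.50,
                            diastolic_width = 0.12,
                            fluid = fluid_properties(),
                            vessel_diameter = 4) {
  if (cycle_duration <= 0) stop("cycle_duration must be positive")
  if (base_level <= 0 || systolic_amp < 0 || diastolic_amp < 0)
    stop("waveform requires base_level > 0 and non-negative amplitudes")
  nu <- fluid$kinematic_viscosity
  D <- vessel_diameter * 1e-3
  if (is.null(peak_velocity)) peak_velocity <- reynolds * nu / D

  wf <- list(cycle_duration = cycle_duration, peak_velocity = peak_velocity,
             base_level = base_level,
             systolic_amp = systolic_amp,
             systolic_peak_phase = systolic_peak_phase,
             systolic_width = systolic_width,
             diastolic_amp = diastolic_amp, diastolic_phase = diastolic_phase,
             diastolic_width = diastolic_width,
             vessel_diameter = vessel_diameter)

  # normalize: locate the exact cycle maximum of the raw shape
  phi <- seq(0, 1, length.out = 4097)[-4097]
  raw <- waveform_raw(wf, phi)
  i0 <- which.max(raw)
  opt <- stats::optimize(function(p) -waveform_raw(wf, p),
                         lower = phi[i0] - 2 / 4096,
                         upper = phi[i0] + 2 / 4096, tol = 1e-14)
  wf$peak_phase <- opt$minimum
  wf$norm <- waveform_raw(wf, wf$peak_phase)
  wf$mean_rel <- mean(raw) / wf$norm
  wf$reynolds <- reynolds_number(peak_velocity, D, nu)
  wf$womersley <- womersley_number(D, cycle_duration, nu)
  class(wf) <- "aneupiv_waveform"
  wf
}

# raw (unnormalized) waveform shape at cycle fraction phi
waveform_raw <- function(wf, phi) {
  phi <- phi %% 1
  pgauss <- function(phi, mu, s) {
    d <- abs(phi - mu)
    d <- pmin(d, 1 - d)
    exp(-d^2 / (2 * s^2))
  }
  wf$base_level +
    wf$systolic_amp * pgauss(phi, wf$systolic_peak_phase, wf$systolic_width) +
    wf$diastolic_amp * pgauss(phi, wf$diastolic_phase, wf$diastolic_width)
}

#' Evaluate the normalized waveform
#'
#' @param wf An `aneupiv_waveform`.
#' @param t Time (s), any real; the waveform is periodic with period
#'   `cycle_duration`.
#' @param peak_damping Optional fractional damping of the systolic peak
#'   component (0 = none), used by treatment scenarios.
#' @return Waveform values in (0, 1], equal to 1 at the systolic peak.
#' @export
waveform_eval <- function(wf, t, peak_damping = 0) {
  phi <- (t / wf$cycle_duration) %% 1
  if (peak_damping > 0) {
    wfd <- wf
    wfd$systolic_amp <- wf$systolic_amp * (1 - peak_damping)
    waveform_raw(wfd, phi) / wf$norm
  } else {
    waveform_raw(wf, phi) / wf$norm
  }
}

#' @export
print.aneupiv_waveform <- function(x, ...) {
  cat(sprintf(
    "Pulsatile waveform: T = %g s, U_peak = %.4g m/s (Re = %.0f, Wo = %.3g)\n",
    x$cycle_duration, x$peak_velocity, x$reynolds, x$womersley))
  cat(sprintf("  systolic peak at phase %.3f, cycle mean/max = %.3f\n",
              x$peak_phase, x$mean_rel))
  invisible(x)
}
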