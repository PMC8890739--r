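#' ROI-mean velocity of a phase-averaged cycle
#'
#' Spatial-mean speed over the region of interest, summarized over the
#' cycle: `cyclic_mean` is the time average of the ROI spatial-mean speed,
#' `cyclic_max` its maximum over phases (peak systole).
#'
#' @param pac An `aneupiv_phase_cycle`.
#' @param roi_mask Logical `ny x nx` matrix; must select at least one grid
#'   point.
#' @param mode `"cyclic_mean"` or `"cyclic_max"`.
#' @param bias_correct Subtract the per-phase across-cycle variance over
#'   the cycle count from the squared phase-mean speed before taking the
#'   magnitude (the standard unbiased correction of a mean-speed map:
#'   with N cycles, `E|v_bar|^2 = |mu|^2 + sum(var)/N`, so the raw
#'   magnitude is inflated by noise and fluctuation rectification at
#'   small N). Requires per-phase deviations (N >= 2).
#' @return Scalar speed (m/s).
#' @export
roi_mean_speed <- function(pac, roi_mask, mode = c("cyclic_mean",
                                                   "cyclic_max"),
                           bias_correct = FALSE) {
  mode <- match.arg(mode)
  if (!any(roi_mask)) stop("empty ROI mask")
  series <- roi_speed_series(pac, roi_mask, bias_correct = bias_correct)
  if (mode == "cyclic_mean") mean(series) else max(series)
}

#' Relative velocity reduction
#'
#' `100 * (1 - treated / untreated)` percent; the headline value is the
#' nearest-integer percent, the unrounded value is always carried.
#'
#' @param treated,untreated ROI-mean speeds (m/s); `untreated` must be
#'   positive.
#' @return List with `percent` (unrounded) and `percent_rounded`.
#' @export
velocity_reduction <- function(treated, untreated) {
  if (untreated <= 0) stop("untreated reference velocity must be positive")
  pct <- 100 * (1 - treated / untreated)
  list(percent = pct, percent_rounded = round(pct))
}

#' Normalized out-of-plane fluctuation
#'
#' Cycle-and-ROI mean of the per-phase standard deviation of the
#' out-of-plane velocity component, normalized by the scenario's own
#' cycle-averaged ROI-mean speed (U_z_STD / U_mean). The default averages
#' the standard deviation over the ROI first and normalizes once
#' (`normalize = "after"`); `normalize = "before"` divides pointwise by the
#' local cycle-mean speed before averaging.
#'
#' A known measurement-noise standard deviation of the out-of-plane
#' component (scalar or one value per phase, see [estimate_oop_noise()])
#' can be removed in quadrature via `noise_sd`; physical fluctuation
#' below the noise floor clips to zero.
#'
#' @param pac An `aneupiv_phase_cycle` with at least two cycles.
#' @param roi_mask Logical `ny x nx` matrix.
#' @param u_mean Optional normalization speed (m/s); defaults to
#'   `roi_mean_speed(pac, roi_mask, "cyclic_mean")`.
#' @param noise_sd Out-of-plane measurement-noise standard deviation (m/s,
#'   scalar or per phase) removed from the deviations.
#' @param normalize `"after"` (default) or `"before"`.
#' @param estimator `"mean_sd"` (default): ROI mean of the per-point
#'   standard deviation, the convention of the reference table;
#'   `"pooled_rms"`: square root of the noise-subtracted ROI-and-phase
#'   pooled variance. Ratios of `"pooled_rms"` values between scenarios
#'   cancel both the spatial-heterogeneity factor and the spatial
#'   attenuation of the measurement chain, so that estimator is preferred
#'   for fold-increase comparisons under measurement noise.
#' @return Dimensionless fluctuation ratio.
#' @export
oop_fluctuation_ratio <- function(pac, roi_mask, u_mean = NULL,
                                  noise_sd = 0,
                                  normalize = c("after", "before"),
                                  estimator = c("mean_sd", "pooled_rms")) {
  normalize <- match.arg(normalize)
  estimator <- match.arg(estimator)
  stopifnot(inherits(pac, "aneupiv_phase_cycle"))
  if (is.null(pac$sd))
    stop("per-phase standard deviations require at least two cycles")
  if (!any(roi_mask)) stop("empty ROI mask")
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, pac$n_phases)
  stopifnot(length(noise_sd) == pac$n_phases)
  idx <- which(roi_mask)
  M <- pac$n_phases

  if (estimator == "pooled_rms") {
    v_p <- vapply(seq_len(M), function(p) {
      mean(pac$sd[, , 3, p][idx]^2, na.rm = TRUE) - noise_sd[p]^2
    }, 0)
    num <- sqrt(max(mean(v_p), 0))
    u_mean <- u_mean %||% roi_mean_speed(pac, roi_mask, "cyclic_mean")
    if (u_mean <= 0) stop("U_mean must be positive")
    return(num / u_mean)
  }

  # mean-of-sd estimator; the noise correction scales each phase's
  # ROI-mean deviation by the pooled noise fraction, which avoids the
  # clipping bias of a pointwise quadrature subtraction
  per_phase <- matrix(NA_real_, length(idx), M)
  for (p in seq_len(M)) {
    s_p <- pac$sd[, , 3, p][idx]
    if (noise_sd[p] > 0) {
      ms2 <- mean(s_p^2, na.rm = TRUE)
      s_p <- s_p * sqrt(max(1 - noise_sd[p]^2 / ms2, 0))
    }
    per_phase[, p] <- s_p
  }
  if (normalize == "after") {
    u_mean <- u_mean %||% roi_mean_speed(pac, roi_mask, "cyclic_mean")
    if (u_mean <= 0) stop("U_mean must be positive")
    mean(per_phase, na.rm = TRUE) / u_mean
  } else {
    local_mean <- cycle_average(pac)$speed[idx]
    ok <- local_mean > 0
    mean(sweep(per_phase[ok, , drop = FALSE], 1, local_mean[ok], "/"),
         na.rm = TRUE)
  }
}

#' Estimate the out-of-plane measurement-noise floor
#'
#' The symmetric stereo rig solves four projected-displacement equations
#' for three velocity components; the redundant direction is the
#' disparity of the two cameras' v displacements, `dv1 - dv2`, which is
#' blind to the flow and measures the camera-independent displacement
#' noise (sensor noise, sampling-through-the-sheet parallax). Because the
#' out-of-plane component is reconstructed from the analogous u
#' disparity, `w_noise = m / (2 sin(theta) dt) * sd_c(dv1 - dv2)`
#' estimates the standard deviation of the out-of-plane measurement
#' noise, per phase, where `sd_c` is the deviation across cycles at fixed
#' phase and location: exactly the part of the noise that contaminates
#' the cycle-to-cycle fluctuation statistics. Noise common to both
#' cameras (identical tracer pattern) cancels in both disparities, and
#' static per-location biases drop out of the across-cycle deviation.
#'
#' @param fields List over cycles of lists over phases of
#'   `aneupiv_velocity_field`s carrying `v_resid` (as produced by
#'   [stereo_reconstruct()]).
#' @param roi_mask Logical ROI matrix on the vector grid.
#' @param view_angle Stereo half-angle (degrees).
#' @param magnification Magnification (um/px).
#' @return Numeric vector of per-phase out-of-plane noise standard
#'   deviations (m/s).
#' @export
estimate_oop_noise <- function(fields, roi_mask, view_angle = 35,
                               magnification = 44.0625) {
  M <- length(fields[[1]])
  N <- length(fields)
  th <- view_angle * pi / 180
  m_mm <- magnification / 1000
  vapply(seq_len(M), function(p) {
    stack <- vapply(fields, function(cyc) {
      f <- cyc[[p]]
      r <- f$v_resid
      r[!roi_mask | f$flags == "masked"] <- NA
      as.vector(r)
    }, numeric(length(fields[[1]][[p]]$v_resid)))
    cnt <- rowSums(!is.na(stack))
    keep <- cnt >= 2
    if (sum(keep) < 8) return(0)
    mu <- rowMeans(stack[keep, , drop = FALSE], na.rm = TRUE)
    v <- rowSums((stack[keep, , drop = FALSE] - mu)^2, na.rm = TRUE) /
      (cnt[keep] - 1)
    m_mm / (2 * sin(th) * fields[[1]][[p]]$dt_us) * sqrt(mean(v)) * 1000
  }, 0)
}

#' Out-of-plane fluctuation amplitude from spatial lag covariance
#'
#' A noise-free estimator of the cycle-to-cycle out-of-plane fluctuation
#' amplitude: the across-cycle covariance between vector locations two
#' grid steps apart (one full interrogation window, so their
#' measurement-noise contributions share no pixels and are uncorrelated)
#' retains only the spatially smooth physical fluctuation (locations a
#' window-and-a-half apart share no pixels and, with the default lag, no
#' particle images either). The square root of the pooled lag covariance estimates the fluctuation amplitude
#' times the square root of the signal's spatial correlation at the lag
#' distance; that factor, like the window-response attenuation, is a
#' property of the disturbance field and the instrument, identical
#' across treatment scenarios, so ratios of this amplitude between
#' scenarios estimate the underlying fluctuation ratio without any
#' noise-floor model.
#'
#' @param fields List over cycles of lists over phases of
#'   `aneupiv_velocity_field`s.
#' @param roi_mask Logical ROI matrix on the vector grid.
#' @param lag Grid-step separation. The default 3 (one and a half
#'   windows at 50 percent overlap) leaves a clear gap between the two
#'   interrogation windows, so that not even particle images smeared by
#'   the light-sheet parallax contribute to both; lag 2 windows abut and
#'   retain a small shared-particle noise covariance.
#' @return Fluctuation amplitude (m/s, attenuated by the spatial
#'   correlation factor; use ratios between scenarios).
#' @export
oop_lagcov_amplitude <- function(fields, roi_mask, lag = 3L) {
  N <- length(fields)
  if (N < 2) stop("need at least two cycles")
  M <- length(fields[[1]])
  per_phase <- rep(NA_real_, M)
  for (p in seq_len(M)) {
    ws <- lapply(fields, function(cyc) {
      w <- cyc[[p]]$w
      w[!roi_mask | cyc[[p]]$flags == "masked"] <- NA
      w
    })
    stack <- array(unlist(ws), c(dim(ws[[1]]), N))
    mu <- apply(stack, c(1, 2), mean)
    delta <- sweep(stack, c(1, 2), mu)
    ny <- nrow(mu); nx <- ncol(mu)
    # pairs along x
    a <- delta[, seq_len(nx - lag), , drop = FALSE]
    b <- delta[, lag + seq_len(nx - lag), , drop = FALSE]
    prod_x <- apply(a * b, c(1, 2), sum) / (N - 1)
    # pairs along y
    a2 <- delta[seq_len(ny - lag), , , drop = FALSE]
    b2 <- delta[lag + seq_len(ny - lag), , , drop = FALSE]
    prod_y <- apply(a2 * b2, c(1, 2), sum) / (N - 1)
    vals <- c(prod_x, prod_y)
    vals <- vals[is.finite(vals)]
    if (length(vals)) per_phase[p] <- mean(vals)
  }
  if (all(is.na(per_phase))) return(0)
  # median across phases: the pooled covariance is robust against the
  # occasional phase whose ROI contains clusters of spurious vectors
  sqrt(max(median(per_phase, na.rm = TRUE), 0))
}

#' Oscillatory velocity index map
#'
#' Pointwise `OVI = 1/2 (1 - ||int v dt|| / int ||v|| dt)` over one cycle
#' (periodic trapezoid integration on the uniform phase grid), with the
#' Euclidean norm over all three components by default; `components =
#' "inplane"` restricts the norm to the in-plane components for sensitivity
#' checks. OVI is 0 for unidirectional flow and 0.5 for fully oscillating
#' flow with zero net transport. Points whose path integral
#' `int ||v|| dt` falls below `floor` (stagnation) return 0: no transport
#' supports no oscillation claim, and the map stays total and bounded.
#'
#' @param pac An `aneupiv_phase_cycle`.
#' @param components `"all"` (3-component) or `"inplane"`.
#' @param floor Denominator floor (m).
#' @return `ny x nx` matrix with values in [0, 0.5].
#' @export
ovi_map <- function(pac, components = c("all", "inplane"), floor = 1e-9) {
  components <- match.arg(components)
  stopifnot(inherits(pac, "aneupiv_phase_cycle"))
  nc <- if (components == "all") 3 else 2
  m <- pac$mean[, , seq_len(nc), , drop = FALSE]
  net <- apply(m, c(1, 2, 3), mean)                       # mean vector
  net_norm <- sqrt(apply(net^2, c(1, 2), sum))
  sp <- sqrt(apply(m^2, c(1, 2, 4), sum))                 # speed per phase
  path <- apply(sp, c(1, 2), mean)
  Tdur <- pac$cycle_duration
  out <- 0.5 * (1 - net_norm / path)
  out[path * Tdur < floor] <- 0
  out[is.na(out)] <- 0
  pmin(pmax(out, 0), 0.5)
}

#' Probe velocity time series
#'
#' Bilinear interpolation of the phase-averaged speed at probe locations,
#' one series per probe over the cycle.
#'
#' @param pac An `aneupiv_phase_cycle`.
#' @param probes `n x 2` matrix of probe (x, y) in mm (e.g.
#'   `geometry$probes`).
#' @return List with `time` (phase times, s) and `speed` (`M x n` matrix,
#'   m/s), columns named by probe.
#' @export
probe_timeseries <- function(pac, probes) {
  stopifnot(inherits(pac, "aneupiv_phase_cycle"))
  if (is.null(dim(probes))) probes <- matrix(probes, nrow = 1)
  M <- pac$n_phases
  sp <- array(0, c(length(pac$y), length(pac$x), M))
  for (p in seq_len(M)) {
    sp[, , p] <- sqrt(pac$mean[, , 1, p]^2 + pac$mean[, , 2, p]^2 +
                        pac$mean[, , 3, p]^2)
  }
  out <- matrix(NA_real_, M, nrow(probes))
  colnames(out) <- rownames(probes) %||% paste0("P", seq_len(nrow(probes)))
  for (i in seq_len(nrow(probes))) {
    out[, i] <- bilinear_series(sp, pac$x, pac$y, probes[i, 1], probes[i, 2])
  }
  list(time = (seq_len(M) - 1) * pac$phase_duration, speed = out)
}

# bilinear interpolation of a (ny, nx, M) stack at one (x0, y0)
bilinear_series <- function(arr, x, y, x0, y0) {
  if (x0 < min(x) || x0 > max(x) || y0 < min(y) || y0 > max(y))
    stop("probe outside the field grid")
  jx <- findInterval(x0, x, all.inside = TRUE)
  iy <- findInterval(y0, y, all.inside = TRUE)
  tx <- (x0 - x[jx]) / (x[jx + 1] - x[jx])
  ty <- (y0 - y[iy]) / (y[iy + 1] - y[iy])
  a00 <- arr[iy, jx, ]; a01 <- arr[iy, jx + 1, ]
  a10 <- arr[iy + 1, jx, ]; a11 <- arr[iy + 1, jx + 1, ]
  if (anyNA(c(a00, a01, a10, a11)))
    stop("probe lies in a masked region of the field")
  (1 - ty) * ((1 - tx) * a00 + tx * a01) + ty * ((1 - tx) * a10 + tx * a11)
}

#' Build a hemodynamic report across scenarios
#'
#' Collects the quantitative efficacy measures for a set of
#' phase-averaged scenario measurements: ROI-mean velocities (cyclic mean
#' and max), relative reductions against the untreated reference,
#' normalized out-of-plane fluctuations and their increase over baseline,
#' OVI maps, and probe time series.
#'
#' @param pacs Named list of `aneupiv_phase_cycle`s, one per scenario; must
#'   contain the untreated reference.
#' @param geom The `aneupiv_geometry`.
#' @param untreated Name of the untreated reference scenario.
#' @param noise_sd Named numeric (or single value) of out-of-plane noise
#'   floors per scenario, passed to [oop_fluctuation_ratio()].
#' @return Object of class `aneupiv_report`: data frame `table` with one
#'   row per scenario (`u_mean_cyclic_mean`, `u_mean_cyclic_max`,
#'   `reduction_mean_pct`, `reduction_max_pct`, `oop_ratio`,
#'   `oop_increase`), plus `ovi` (list of maps) and `probes` (list of
#'   series).
#' @export
hemodynamic_report <- function(pacs, geom, untreated = "noFD",
                               noise_sd = 0) {
  stopifnot(untreated %in% names(pacs))
  ns <- names(pacs)
  if (length(noise_sd) == 1 && is.null(names(noise_sd)))
    noise_sd <- setNames(rep(noise_sd, length(ns)), ns)
  rows <- list(); ovi <- list(); probes <- list()
  for (nm in ns) {
    pac <- pacs[[nm]]
    roi <- roi_mask_for(geom, pac$x, pac$y)
    um <- roi_mean_speed(pac, roi, "cyclic_mean")
    ux <- roi_mean_speed(pac, roi, "cyclic_max")
    oop <- if (!is.null(pac$sd))
      oop_fluctuation_ratio(pac, roi, noise_sd = noise_sd[[nm]]) else NA_real_
    rows[[nm]] <- data.frame(scenario = nm, u_mean_cyclic_mean = um,
                             u_mean_cyclic_max = ux, oop_ratio = oop)
    ovi[[nm]] <- ovi_map(pac)
    probes[[nm]] <- probe_timeseries(pac, geom$probes)
  }
  tab <- do.call(rbind, rows)
  ref <- tab[tab$scenario == untreated, ]
  tab$reduction_mean_pct <-
    100 * (1 - tab$u_mean_cyclic_mean / ref$u_mean_cyclic_mean)
  tab$reduction_max_pct <-
    100 * (1 - tab$u_mean_cyclic_max / ref$u_mean_cyclic_max)
  tab$oop_increase <- tab$oop_ratio / ref$oop_ratio
  rownames(tab) <- NULL
  structure(list(table = tab, ovi = ovi, probes = probes,
                 untreated = untreated),
            class = "aneupiv_report")
}

#' @export
print.aneupiv_report <- function(x, ...) {
  cat("Hemodynamic efficacy report (reference:", x$untreated, ")\n")
  tab <- x$table
  tab$u_mean_cyclic_mean <- signif(tab$u_mean_cyclic_mean, 3)
  tab$u_mean_cyclic_max <- signif(tab$u_mean_cyclic_max, 3)
  tab$reduction_mean_pct <- round(tab$reduction_mean_pct)
  tab$reduction_max_pct <- round(tab$reduction_max_pct)
  tab$oop_ratio <- signif(tab$oop_ratio, 3)
  tab$oop_increase <- signif(tab$oop_increase, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a hemodynamic report to JSON and CSV
#'
#' @param report An `aneupiv_report`.
#' @param dir Output directory.
#' @return Invisibly, the file paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fj <- file.path(dir, "report.json")
  fc <- file.path(dir, "report.csv")
  jsonlite::write_json(
    list(table = report$table,
         ovi_range = lapply(report$ovi, range),
         untreated = report$untreated),
    fj, auto_unbox = TRUE, digits = NA)
  write.csv(report$table, fc, row.names = FALSE)
  invisible(c(fj, fc))
}
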