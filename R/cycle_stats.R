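#' Phase-average trigger-locked velocity recordings
#'
#' Averages velocity fields recorded at the same cardiac-cycle phase over
#' many cycles: pointwise mean and (for two or more cycles) the unbiased
#' (N-1) standard deviation per phase. Grid points missing in some cycles
#' (masked or rejected vectors) are averaged over the cycles where they are
#' present; points missing everywhere stay `NA` (masked propagates as
#' masked).
#'
#' @param recordings A list over cycles; each element is a list over phases
#'   of `aneupiv_velocity_field`s (or plain lists with `u`, `v`, `w`
#'   matrices and grid vectors `x`, `y`). All cycles must share the same
#'   phase count and spatial grid.
#' @param cycle_duration Cycle duration T (s); the phase duration is
#'   `T / M`.
#' @return Object of class `aneupiv_phase_cycle`: arrays `mean` and `sd`
#'   (`ny x nx x 3 x M`; `sd` is `NULL` for a single cycle), grid `x`, `y`
#'   (mm), `n_cycles`, `n_phases`, `phase_duration`, `cycle_duration`.
#' @export
phase_average <- function(recordings, cycle_duration = 1.0) {
  n_cyc <- length(recordings)
  if (n_cyc < 1) stop("need at least one cycle")
  M <- length(recordings[[1]])
  if (M < 1) stop("need at least one phase")
  if (any(vapply(recordings, length, 0L) != M))
    stop("all cycles must provide the same phases")
  f0 <- recordings[[1]][[1]]
  x <- f0$x; y <- f0$y
  ny <- length(y); nx <- length(x)
  for (cyc in recordings) for (f in cyc) {
    if (!isTRUE(all.equal(f$x, x)) || !isTRUE(all.equal(f$y, y)))
      stop("inconsistent spatial grids across recordings")
  }

  mean_arr <- array(NA_real_, c(ny, nx, 3, M))
  sd_arr <- if (n_cyc >= 2) array(NA_real_, c(ny, nx, 3, M)) else NULL
  npt <- ny * nx
  for (p in seq_len(M)) {
    stack <- matrix(NA_real_, npt * 3, n_cyc)
    for (ic in seq_len(n_cyc)) {
      f <- recordings[[ic]][[p]]
      stack[, ic] <- c(f$u, f$v, f$w)
    }
    cnt <- rowSums(!is.na(stack))
    s1 <- rowSums(stack, na.rm = TRUE)
    mu <- ifelse(cnt > 0, s1 / cnt, NA_real_)
    mean_arr[, , , p] <- array(mu, c(ny, nx, 3))
    if (n_cyc >= 2) {
      s2 <- rowSums(stack^2, na.rm = TRUE)
      va <- ifelse(cnt >= 2, pmax(s2 - cnt * mu^2, 0) / (cnt - 1), NA_real_)
      sd_arr[, , , p] <- array(sqrt(va), c(ny, nx, 3))
    }
  }
  structure(list(mean = mean_arr, sd = sd_arr, x = x, y = y,
                 n_cycles = n_cyc, n_phases = M,
                 phase_duration = cycle_duration / M,
                 cycle_duration = cycle_duration),
            class = "aneupiv_phase_cycle")
}

#' @export
print.aneupiv_phase_cycle <- function(x, ...) {
  cat(sprintf(
    "Phase-averaged cycle: %d phases x %d cycles on a %d x %d grid (T = %g s)\n",
    x$n_phases, x$n_cycles, length(x$x), length(x$y),
    x$cycle_duration))
  invisible(x)
}

#' Cycle averages of a phase-averaged cycle
#'
#' Time average over the full cycle (periodic trapezoid in phase, which for
#' the uniform phase grid is the plain mean) of the phase-averaged speed
#' and of the phase-averaged velocity vector. The two differ wherever the
#' flow direction changes over the cycle; the speed map is the
#' strictly-positive quantity reported by treatment studies, the vector map
#' feeds the oscillatory velocity index.
#'
#' @param pac An `aneupiv_phase_cycle`.
#' @return List with `speed` (`ny x nx`, m/s) and `vector`
#'   (`ny x nx x 3`, m/s).
#' @export
cycle_average <- function(pac) {
  stopifnot(inherits(pac, "aneupiv_phase_cycle"))
  sp <- sqrt(pac$mean[, , 1, , drop = FALSE]^2 +
               pac$mean[, , 2, , drop = FALSE]^2 +
               pac$mean[, , 3, , drop = FALSE]^2)
  speed <- apply(sp[, , 1, , drop = FALSE], c(1, 2), mean)
  vector <- apply(pac$mean, c(1, 2, 3), mean)
  list(speed = speed, vector = vector)
}

#' Locate peak systole
#'
#' The phase (1-based index) maximizing the spatial-mean speed over the
#' region of interest; ties break to the lowest index.
#'
#' @param pac An `aneupiv_phase_cycle`.
#' @param roi_mask Logical `ny x nx` matrix (e.g. from [roi_mask_for()]).
#' @return Integer phase index.
#' @export
find_peak_phase <- function(pac, roi_mask) {
  stopifnot(inherits(pac, "aneupiv_phase_cycle"))
  if (!any(roi_mask)) stop("empty ROI mask")
  series <- roi_speed_series(pac, roi_mask)
  which.max(series)   # which.max takes the first maximum: lowest index
}

# spatial-mean speed over the ROI, one value per phase; optionally with
# the unbiased small-sample magnitude correction |mu|^2 ~ |v_bar|^2 -
# sum(var)/N
roi_speed_series <- function(pac, roi_mask, bias_correct = FALSE) {
  if (bias_correct && (is.null(pac$sd) || pac$n_cycles < 2))
    stop("bias correction requires per-phase deviations (N >= 2 cycles)")
  vapply(seq_len(pac$n_phases), function(p) {
    sp2 <- pac$mean[, , 1, p]^2 + pac$mean[, , 2, p]^2 +
      pac$mean[, , 3, p]^2
    if (bias_correct) {
      sp2 <- sp2 - (pac$sd[, , 1, p]^2 + pac$sd[, , 2, p]^2 +
                      pac$sd[, , 3, p]^2) / pac$n_cycles
    }
    mean(sqrt(pmax(sp2, 0))[roi_mask], na.rm = TRUE)
  }, 0)
}

#' Region-of-interest mask on an arbitrary grid
#'
#' Rasterizes the sac ROI (optionally shrunk inward by `margin` mm) onto
#' the grid spanned by coordinate vectors `x`, `y`.
#'
#' @param geom An `aneupiv_geometry`.
#' @param x,y Grid coordinate vectors (mm).
#' @param margin Inward margin from the sac wall (mm).
#' @return Logical `length(y) x length(x)` matrix.
#' @export
roi_mask_for <- function(geom, x, y, margin = 0) {
  X <- matrix(x, length(y), length(x), byrow = TRUE)
  Y <- matrix(y, length(y), length(x))
  r2 <- (X - geom$sac_center[1])^2 + (Y - geom$sac_center[2])^2
  r2 <= (geom$sac_radius - margin)^2 & Y > geom$vessel_halfwidth
}

#' Lumen mask on an arbitrary grid
#'
#' @inheritParams roi_mask_for
#' @return Logical `length(y) x length(x)` matrix.
#' @export
lumen_mask_for <- function(geom, x, y) {
  X <- matrix(x, length(y), length(x), byrow = TRUE)
  Y <- matrix(y, length(y), length(x))
  matrix(in_lumen(geom, as.vector(X), as.vector(Y)), length(y), length(x))
}
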