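#' PIV processing configuration
#'
#' Multi-pass cross-correlation settings. Defaults follow standard
#' stereo-PIV practice: two passes with 64 then 32 px interrogation
#' windows, 50 % overlap (one vector every 16 px, i.e. every 141 um at the
#' reference magnification), 3-point Gaussian sub-pixel peak fitting, and
#' normalized-median outlier validation.
#'
#' @param windows Integer vector of per-pass window sizes (px), strictly
#'   decreasing powers of two.
#' @param overlap Window overlap fraction in [0, 1).
#' @param subpixel Sub-pixel estimator (only `"gauss3pt"` implemented).
#' @param validation_threshold Normalized-median residual threshold.
#' @param min_peak_ratio Minimum first-to-second correlation peak ratio for
#'   a vector to count as valid.
#' @return Object of class `aneupiv_piv_config`.
#' @export
piv_config <- function(windows = c(64L, 32L), overlap = 0.5,
                       subpixel = "gauss3pt", validation_threshold = 2,
                       min_peak_ratio = 1.2) {
  windows <- as.integer(windows)
  if (any(diff(windows) >= 0)) stop("window sizes must be strictly decreasing")
  if (any(bitwAnd(windows, windows - 1L) != 0L))
    stop("window sizes must be powers of two")
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  subpixel <- match.arg(subpixel, "gauss3pt")
  structure(list(windows = windows, overlap = overlap, subpixel = subpixel,
                 validation_threshold = validation_threshold,
                 min_peak_ratio = min_peak_ratio),
            class = "aneupiv_piv_config")
}

#' Cross-correlate one window pair
#'
#' FFT cross-correlation of two equal square intensity tiles with per-tile
#' mean subtraction, 3-point Gaussian sub-pixel refinement, and
#' first-to-second peak ratio. The displacement is that of `window_b`
#' relative to `window_a` (x = columns, y = rows, px).
#'
#' @param window_a,window_b Equal-size square numeric matrices.
#' @return List with `dx`, `dy` (px), `peak_ratio`, and `status`
#'   (`"ok"`, `"flat"`, or `"out_of_range"` for displacements beyond a
#'   quarter window).
#' @export
cross_correlate <- function(window_a, window_b) {
  if (!identical(dim(window_a), dim(window_b)) ||
      nrow(window_a) != ncol(window_a))
    stop("windows must be equal square tiles")
  r <- cpp_xcorr_tile(window_a, window_b)
  if (r[4] == 1) stop("constant tile: no correlation peak")
  list(dx = r[1], dy = r[2], peak_ratio = r[3],
       status = c("ok", "flat", "out_of_range")[r[4] + 1])
}

# vector grid (window centers, px) for a given pass
.piv_grid <- function(dim_xy, win, pitch, margin) {
  list(cx = seq.int(margin + 1L, dim_xy[1] - margin, by = pitch),
       cy = seq.int(margin + 1L, dim_xy[2] - margin, by = pitch))
}

#' Multi-pass PIV on one image pair
#'
#' Coarse-to-fine cross-correlation: each pass correlates interrogation
#' windows centered on the vector grid, with the second frame's window
#' offset by the (rounded) displacement predicted by the previous pass.
#' Each intermediate field is validated with the normalized-median test
#' before being used as predictor. Windows whose center lies outside the
#' mask produce masked vectors.
#'
#' @param pair An `aneupiv_image_pair`.
#' @param config A [piv_config()].
#' @param mask Optional logical matrix of the sensor (row = v, col = u);
#'   `TRUE` where vectors should be computed.
#' @return Object of class `aneupiv_disp_field`: matrices `dx`, `dy` (px),
#'   `peak_ratio`, `flags` (`"valid"`, `"replaced"`, `"masked"`), vector
#'   pixel coordinates `cx`, `cy`, `pitch`, `window`, and the pair's
#'   `dt_us`, `phase`, `cycle`.
#' @export
multipass_piv <- function(pair, config = piv_config(), mask = NULL) {
  stopifnot(inherits(pair, "aneupiv_image_pair"))
  A <- pair$frame_a; B <- pair$frame_b
  if (!identical(dim(A), dim(B))) stop("frames must have identical shapes")
  dim_xy <- c(ncol(A), nrow(A))
  if (any(config$windows[1] > dim_xy))
    stop("image smaller than the largest interrogation window")
  final_win <- config$windows[length(config$windows)]
  pitch <- as.integer(round(final_win * (1 - config$overlap)))
  margin <- config$windows[1] %/% 2L

  fine <- .piv_grid(dim_xy, final_win, pitch, margin)
  nxv <- length(fine$cx); nyv <- length(fine$cy)
  CX <- matrix(fine$cx, nyv, nxv, byrow = TRUE)
  CY <- matrix(fine$cy, nyv, nxv)
  in_mask <- if (is.null(mask)) matrix(TRUE, nyv, nxv) else
    matrix(mask[cbind(as.vector(CY), as.vector(CX))], nyv, nxv)

  pass_field <- function(grid, win, pred_x, pred_y, in_mask_g) {
    nyg <- length(grid$cy); nxg <- length(grid$cx)
    gCX <- matrix(grid$cx, nyg, nxg, byrow = TRUE)
    gCY <- matrix(grid$cy, nyg, nxg)
    idx <- which(in_mask_g)
    r <- cpp_correlate_windows(A, B, as.vector(gCX)[idx], as.vector(gCY)[idx],
                               win, as.vector(pred_x)[idx],
                               as.vector(pred_y)[idx])
    dx <- dy <- ratio <- matrix(NA_real_, nyg, nxg)
    ok <- matrix(FALSE, nyg, nxg)
    dx[idx] <- r[, 1]; dy[idx] <- r[, 2]; ratio[idx] <- r[, 3]
    ok[idx] <- r[, 4] == 0 & r[, 3] >= config$min_peak_ratio
    bad_idx <- idx[r[, 4] != 0]
    dx[bad_idx] <- NA; dy[bad_idx] <- NA
    fld <- structure(list(dx = dx, dy = dy, peak_ratio = ratio,
                          flags = ifelse(in_mask_g,
                                         ifelse(ok, "valid", "replaced"),
                                         "masked"),
                          cx = grid$cx, cy = grid$cy,
                          pitch = as.integer(round(win * (1 - config$overlap))),
                          window = win, dt_us = pair$dt_us,
                          phase = pair$phase, cycle = pair$cycle),
                     class = "aneupiv_disp_field")
    validate_replace(fld, config$validation_threshold, quiet = TRUE)
  }
  grid_mask <- function(grid) {
    nyg <- length(grid$cy); nxg <- length(grid$cx)
    if (is.null(mask)) return(matrix(TRUE, nyg, nxg))
    gCX <- matrix(grid$cx, nyg, nxg, byrow = TRUE)
    gCY <- matrix(grid$cy, nyg, nxg)
    matrix(mask[cbind(as.vector(gCY), as.vector(gCX))], nyg, nxg)
  }

  # coarse passes run on their own (coarser) grids and provide integer
  # predictors for the next pass by nearest-node lookup
  pred_x <- matrix(0L, nyv, nxv)
  pred_y <- matrix(0L, nyv, nxv)
  n_pass <- length(config$windows)
  for (ipass in seq_len(n_pass - 1L)) {
    win <- config$windows[ipass]
    gpitch <- as.integer(round(win * (1 - config$overlap)))
    grid <- .piv_grid(dim_xy, win, gpitch, margin)
    zero <- matrix(0L, length(grid$cy), length(grid$cx))
    fld <- pass_field(grid, win, zero, zero, grid_mask(grid))
    nearest <- function(fine_c, coarse_c) {
      vapply(fine_c, function(v) which.min(abs(coarse_c - v)), 0L)
    }
    jx <- nearest(fine$cx, grid$cx)
    jy <- nearest(fine$cy, grid$cy)
    dxn <- fld$dx[jy, jx, drop = FALSE]
    dyn <- fld$dy[jy, jx, drop = FALSE]
    pred_x <- matrix(as.integer(round(ifelse(is.na(dxn), 0, dxn))), nyv, nxv)
    pred_y <- matrix(as.integer(round(ifelse(is.na(dyn), 0, dyn))), nyv, nxv)
  }
  pass_field(fine, final_win, pred_x, pred_y, in_mask)
}

#' Normalized-median outlier validation
#'
#' Flags vectors whose normalized median residual over the 3x3 neighborhood
#' (noise floor 0.1 px) exceeds `threshold` in either component, replaces
#' them (and any missing vectors) by the neighborhood component-wise
#' median, and marks them `"replaced"`. Warns when more than 10 % of
#' unmasked vectors are replaced.
#'
#' @param field An `aneupiv_disp_field` on at least a 3x3 grid.
#' @param threshold Residual threshold (default 2).
#' @param quiet Suppress the replacement-fraction warning.
#' @return The validated field; attribute `replaced_fraction` reports the
#'   fraction of unmasked vectors replaced.
#' @export
validate_replace <- function(field, threshold = 2, quiet = FALSE) {
  stopifnot(inherits(field, "aneupiv_disp_field"))
  nyv <- nrow(field$dx); nxv <- ncol(field$dx)
  if (nyv < 3 || nxv < 3) stop("validation needs at least a 3x3 vector grid")
  masked <- field$flags == "masked"
  dx <- field$dx; dy <- field$dy
  dx[masked] <- NA; dy[masked] <- NA

  neigh_stats <- function(d) {
    med <- matrix(NA_real_, nyv, nxv)
    resmed <- matrix(NA_real_, nyv, nxv)
    for (j in seq_len(nxv)) {
      j0 <- max(1, j - 1); j1 <- min(nxv, j + 1)
      for (i in seq_len(nyv)) {
        i0 <- max(1, i - 1); i1 <- min(nyv, i + 1)
        nb <- d[i0:i1, j0:j1]
        nb <- nb[!is.na(nb)]
        cen <- d[i, j]
        if (!is.na(cen)) nb <- nb[-match(cen, nb)]
        if (length(nb) >= 3) {
          m <- median(nb)
          med[i, j] <- m
          resmed[i, j] <- median(abs(nb - m))
        }
      }
    }
    list(med = med, resmed = resmed)
  }
  sx <- neigh_stats(dx)
  sy <- neigh_stats(dy)
  rx <- abs(dx - sx$med) / (sx$resmed + 0.1)
  ry <- abs(dy - sy$med) / (sy$resmed + 0.1)
  bad <- (!masked) & (is.na(dx) | is.na(dy) |
                        pmax(rx, ry, na.rm = TRUE) > threshold)
  bad[is.na(bad)] <- FALSE
  out <- field
  out$dx[bad] <- sx$med[bad]
  out$dy[bad] <- sy$med[bad]
  out$flags[bad & !masked] <- "replaced"
  frac <- sum(bad) / max(1, sum(!masked))
  attr(out, "replaced_fraction") <- frac
  if (!quiet && frac > 0.1)
    warning(sprintf("%.1f%% of vectors replaced by the median filter",
                    100 * frac))
  out
}

#' @export
print.aneupiv_disp_field <- function(x, ...) {
  cat(sprintf(
    "PIV displacement field: %d x %d vectors, pitch %d px, window %d px\n",
    ncol(x$dx), nrow(x$dx), x$pitch, x$window))
  tab <- table(x$flags)
  cat("  flags:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Displacement-fraction histogram (peak-locking diagnostic)
#'
#' Histogram of the fractional parts of the measured displacements; a
#' flat histogram indicates negligible peak locking, spikes at 0 indicate
#' locking toward integer pixel values.
#'
#' @param field An `aneupiv_disp_field`.
#' @param breaks Number of histogram bins over [-0.5, 0.5).
#' @return Named numeric vector of bin proportions.
#' @export
locking_histogram <- function(field, breaks = 10) {
  stopifnot(inherits(field, "aneupiv_disp_field"))
  d <- c(field$dx[field$flags == "valid"],
         field$dy[field$flags == "valid"])
  fr <- (d + 0.5) %% 1 - 0.5
  edges <- seq(-0.5, 0.5, length.out = breaks + 1)
  counts <- tabulate(findInterval(fr, edges, rightmost.closed = TRUE),
                     nbins = breaks)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  stats::setNames(counts / max(1, sum(counts)), sprintf("%.2f", mids))
}
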