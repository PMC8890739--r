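#' Stereoscopic three-component reconstruction
#'
#' Combines the two-component pixel displacement fields of the two cameras
#' into a three-component velocity field on the measurement plane. At every
#' vector location the four projected-displacement equations
#' `J_c . (dx, dy, dz) = (du_c, dv_c)` (camera mapping Jacobians `J_c` in
#' px/mm, one pair of equations per camera) are solved by least squares,
#' and the world displacement is converted to m/s with the interframe
#' time.
#'
#' Both fields must live on the same sensor grid and the two cameras must
#' view the plane from distinct directions; a near-singular projection
#' system raises an error reporting its condition number.
#'
#' @param field_cam1,field_cam2 `aneupiv_disp_field`s from the two cameras
#'   of one recording.
#' @param cam1,cam2 The corresponding `aneupiv_camera`s.
#' @param dt_us Interframe time (us); defaults to the fields' stored value.
#' @return Object of class `aneupiv_velocity_field`: world grid vectors
#'   `x`, `y` (mm), velocity matrices `u`, `v`, `w` (m/s), `flags`, and the
#'   acquisition `phase`, `cycle`.
#' @export
stereo_reconstruct <- function(field_cam1, field_cam2, cam1, cam2,
                               dt_us = NULL) {
  stopifnot(inherits(field_cam1, "aneupiv_disp_field"),
            inherits(field_cam2, "aneupiv_disp_field"))
  if (!identical(field_cam1$cx, field_cam2$cx) ||
      !identical(field_cam1$cy, field_cam2$cy))
    stop("displacement fields must share the same sensor grid")
  dt_us <- dt_us %||% field_cam1$dt_us

  # common world grid: both cameras see identical plane coordinates by
  # construction of the symmetric rig; verify rather than assume
  w1 <- sensor_to_plane(cam1, field_cam1$cx, rep(field_cam1$cy[1],
                                                 length(field_cam1$cx)))
  w2 <- sensor_to_plane(cam2, field_cam2$cx, rep(field_cam2$cy[1],
                                                 length(field_cam2$cx)))
  if (max(abs(w1 - w2)) > 1e-6)
    stop("cameras do not share a common world grid on the plane")
  x_mm <- w1[, 1]
  y_mm <- sensor_to_plane(cam1, rep(field_cam1$cx[1],
                                    length(field_cam1$cy)),
                          field_cam1$cy)[, 2]

  J1 <- camera_jacobian(cam1)
  J2 <- camera_jacobian(cam2)
  A <- rbind(J1, J2)
  M <- crossprod(A)
  rc <- rcond(M)
  if (rc < 1e-8)
    stop(sprintf(
      "ill-conditioned stereo projection (rcond = %.2e): cameras near-parallel",
      rc))
  solver <- solve(M) %*% t(A)   # 3 x 4, constant for linear mappings

  nyv <- nrow(field_cam1$dx); nxv <- ncol(field_cam1$dx)
  b <- rbind(as.vector(field_cam1$dx), as.vector(field_cam1$dy),
             as.vector(field_cam2$dx), as.vector(field_cam2$dy))
  d_mm <- solver %*% ifelse(is.na(b), 0, b)       # px -> mm via Jacobian
  vel <- d_mm / dt_us * 1000                      # mm / us -> m/s
  anyna <- colSums(is.na(b)) > 0
  vel[, anyna] <- NA

  flags <- matrix("valid", nyv, nxv)
  f1 <- field_cam1$flags; f2 <- field_cam2$flags
  flags[f1 == "replaced" | f2 == "replaced"] <- "replaced"
  flags[f1 == "masked" | f2 == "masked"] <- "masked"
  u <- matrix(vel[1, ], nyv, nxv); u[flags == "masked"] <- NA
  v <- matrix(vel[2, ], nyv, nxv); v[flags == "masked"] <- NA
  w <- matrix(vel[3, ], nyv, nxv); w[flags == "masked"] <- NA

  # least-squares disparity residual of the overdetermined system: the
  # two v-equations are redundant, so dv1 - dv2 (px) measures the
  # camera-independent displacement noise and feeds the out-of-plane
  # noise-floor estimate
  v_resid <- field_cam1$dy - field_cam2$dy
  v_resid[flags == "masked"] <- NA

  structure(list(x = x_mm, y = y_mm, u = u, v = v, w = w, flags = flags,
                 v_resid = v_resid,
                 dt_us = dt_us, phase = field_cam1$phase,
                 cycle = field_cam1$cycle),
            class = "aneupiv_velocity_field")
}

#' @export
print.aneupiv_velocity_field <- function(x, ...) {
  cat(sprintf(
    "3C velocity field: %d x %d vectors, x [%.1f, %.1f] mm, y [%.1f, %.1f] mm\n",
    length(x$x), length(x$y), min(x$x), max(x$x), min(x$y), max(x$y)))
  cat(sprintf("  speed range %.4g - %.4g m/s (unmasked)\n",
              min(sqrt(x$u^2 + x$v^2 + x$w^2), na.rm = TRUE),
              max(sqrt(x$u^2 + x$v^2 + x$w^2), na.rm = TRUE)))
  invisible(x)
}
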