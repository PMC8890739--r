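#' Virtual stereoscopic camera
#'
#' Linear (orthographic, magnification-scaled) mapping from world
#' coordinates (mm) to sensor pixel coordinates, viewing the measurement
#' plane from an angle about the y axis:
#' `u = u0 + (cos(theta) (x - cx) + sin(theta) z) / m`,
#' `v = v0 + (y - cy) / m`, with `m` the magnification in mm/px.
#' Two cameras at symmetric angles (+/- theta) share identical pixel grids
#' on the z = 0 plane, so no dewarping stage is needed; the stereo
#' reconstruction consumes the exact mapping gradients.
#'
#' @param view_angle Viewing angle about the y axis (degrees); the two
#'   cameras of a stereo rig use opposite signs.
#' @param sensor Sensor size `c(width, height)` in px.
#' @param magnification Magnification in um/px. The default 8.8125 um/px
#'   puts one final-pass PIV vector every 141 um at a 16 px grid pitch.
#' @param center_world World point (x, y) mm mapped to the sensor center.
#' @param camera_id Identifier string.
#' @return Object of class `aneupiv_camera`.
#' @export
camera_model <- function(view_angle = 35, sensor = c(2560, 2160),
                         magnification = 8.8125, center_world = c(0, 10),
                         camera_id = "cam1") {
  if (abs(cos(view_angle * pi / 180)) < 1e-6)
    stop("view angle too steep: mapping not invertible on the plane")
  structure(list(view_angle = view_angle, sensor = as.integer(sensor),
                 magnification = magnification, center_world = center_world,
                 camera_id = camera_id),
            class = "aneupiv_camera")
}

#' Map world points to sensor pixels
#'
#' @param cam An `aneupiv_camera`.
#' @param points `n x 2` (x, y; z = 0 assumed) or `n x 3` matrix, mm.
#' @return `n x 2` matrix of (u, v) pixel coordinates (1-based, fractional).
#' @export
world_to_sensor <- function(cam, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  z <- if (ncol(points) >= 3) points[, 3] else 0
  th <- cam$view_angle * pi / 180
  m <- cam$magnification / 1000  # mm per px
  u0 <- (cam$sensor[1] + 1) / 2
  v0 <- (cam$sensor[2] + 1) / 2
  cbind(u0 + (cos(th) * (points[, 1] - cam$center_world[1]) + sin(th) * z) / m,
        v0 + (points[, 2] - cam$center_world[2]) / m)
}

#' Map sensor pixels to the measurement plane
#'
#' Inverse of [world_to_sensor()] restricted to the plane `z = 0`.
#'
#' @param cam An `aneupiv_camera`.
#' @param u,v Pixel coordinates.
#' @return `n x 2` matrix of world (x, y) in mm.
#' @export
sensor_to_plane <- function(cam, u, v) {
  th <- cam$view_angle * pi / 180
  m <- cam$magnification / 1000
  u0 <- (cam$sensor[1] + 1) / 2
  v0 <- (cam$sensor[2] + 1) / 2
  cbind((u - u0) * m / cos(th) + cam$center_world[1],
        (v - v0) * m + cam$center_world[2])
}

#' Mapping gradient of a camera at a world point
#'
#' Central-difference Jacobian of the world-to-sensor mapping,
#' `d(u, v) / d(x, y, z)` in px/mm. Used directly by the stereo
#' reconstruction in place of a physical calibration.
#'
#' @param cam An `aneupiv_camera`.
#' @param point Length-3 world point (mm).
#' @param h Step size (mm).
#' @return A `2 x 3` Jacobian matrix.
#' @export
camera_jacobian <- function(cam, point = c(0, 10, 0), h = 1e-3) {
  J <- matrix(0, 2, 3)
  for (k in 1:3) {
    dp <- c(0, 0, 0); dp[k] <- h
    J[, k] <- (world_to_sensor(cam, rbind(point + dp)) -
                 world_to_sensor(cam, rbind(point - dp))) / (2 * h)
  }
  J
}

#' A symmetric stereo camera pair
#'
#' @inheritParams camera_model
#' @return List of two `aneupiv_camera`s at +/- `view_angle`.
#' @export
stereo_rig <- function(view_angle = 35, sensor = c(2560, 2160),
                       magnification = 8.8125, center_world = c(0, 10)) {
  list(camera_model(view_angle, sensor, magnification, center_world, "cam1"),
       camera_model(-view_angle, sensor, magnification, center_world, "cam2"))
}
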