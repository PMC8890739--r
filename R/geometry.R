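#' Geometry configuration for the idealized side-wall aneurysm
#'
#' Describes an idealized spherical side-wall aneurysm (default diameter
#' 20 mm) sitting on a parent vessel (default diameter 4 mm). The parent
#' vessel is modeled straight along x in the sagittal measurement plane; the
#' clinical bend angle of the parent artery is carried as metadata. The sac
#' is a circle of radius `sac_diameter/2` whose center lies above the vessel
#' so that the circle intersects the upper vessel wall in a chord of length
#' `ostium_width` (the neck/ostium).
#'
#' Coordinates are right-handed: x along the parent vessel (flow direction,
#' distal = +x), y toward the sac, z out of the measurement plane. All
#' lengths in mm.
#'
#' @param sac_diameter Sac diameter (mm).
#' @param vessel_diameter Parent-vessel diameter (mm).
#' @param bend_angle Parent-vessel bend angle (degrees); metadata for the
#'   planar model, must lie in (0, 180).
#' @param ostium_width Chord length of the neck opening (mm).
#' @param pitch Grid pitch for masks and ground-truth evaluation (mm).
#'   Default 0.141 mm, one cell per PIV vector at the reference
#'   magnification.
#' @param extent_x,extent_y Plane extent (mm), length-2 numeric.
#' @param jet_entry_frac Position of the inflow-jet entry on the ostium, as
#'   a fraction of the distal ostium half-width.
#' @param jet_target_angle Polar angle (degrees, from the sac center,
#'   0 = distal/+x) of the wall point the jet aims at; the default sends the
#'   jet from the distal neck across the sac onto the proximal upper wall.
#' @return An object of class `aneupiv_geometry_config`.
#' @export
geometry_config <- function(sac_diameter = 20, vessel_diameter = 4,
                            bend_angle = 120, ostium_width = 8,
                            pitch = 0.141,
                            extent_x = c(-11.28, 11.28),
                            extent_y = c(-1.28, 21.28),
                            jet_entry_frac = 0.7,
                            jet_target_angle = 160) {
  if (!(sac_diameter > vessel_diameter && vessel_diameter > 0))
    stop("require sac_diameter > vessel_diameter > 0")
  if (!(bend_angle > 0 && bend_angle < 180))
    stop("bend_angle must lie in (0, 180) degrees")
  if (pitch <= 0) stop("grid pitch must be positive")
  if (pitch > vessel_diameter / 2)
    stop("grid pitch larger than the vessel radius")
  if (ostium_width <= 0 || ostium_width >= sac_diameter)
    stop("ostium_width must lie in (0, sac_diameter)")
  cfg <- list(sac_diameter = sac_diameter, vessel_diameter = vessel_diameter,
              bend_angle = bend_angle, ostium_width = ostium_width,
              pitch = pitch, extent_x = extent_x, extent_y = extent_y,
              jet_entry_frac = jet_entry_frac,
              jet_target_angle = jet_target_angle)
  class(cfg) <- "aneupiv_geometry_config"
  cfg
}

#' Build geometry masks and landmarks
#'
#' Rasterizes the lumen onto a cell-centered grid and derives the landmarks
#' used downstream: sac / vessel / lumen masks, the region of interest (the
#' sac only), the ostium segment, and the three velocity probes
#' P1 (inflow jet, 2 mm inside the ostium along the jet axis),
#' P2 (aneurysm dome, 1.5 mm inside the apex) and
#' P3 (2 mm inside the proximal ostium edge).
#'
#' @param config A [geometry_config()].
#' @return An object of class `aneupiv_geometry`: grid coordinates `x`, `y`
#'   (mm, cell centers), logical masks `sac_mask`, `vessel_mask`,
#'   `lumen_mask`, `roi_mask` (rows index y, columns x), ostium endpoints,
#'   sac center/radius, jet entry point and direction, and a 3 x 2 probe
#'   matrix.
#' @export
build_geometry <- function(config = geometry_config()) {
  stopifnot(inherits(config, "aneupiv_geometry_config"))
  R_s <- config$sac_diameter / 2
  R_v <- config$vessel_diameter / 2
  a <- config$ostium_width / 2
  y_c <- R_v + sqrt(R_s^2 - a^2)
  sac_center <- c(0, y_c)

  p <- config$pitch
  x <- seq(config$extent_x[1] + p / 2, config$extent_x[2] - p / 2, by = p)
  y <- seq(config$extent_y[1] + p / 2, config$extent_y[2] - p / 2, by = p)
  X <- matrix(x, nrow = length(y), ncol = length(x), byrow = TRUE)
  Y <- matrix(y, nrow = length(y), ncol = length(x))

  r2 <- (X - sac_center[1])^2 + (Y - sac_center[2])^2
  sac_mask <- r2 <= R_s^2 & Y > R_v
  vessel_mask <- abs(Y) <= R_v
  lumen_mask <- sac_mask | vessel_mask
  roi_mask <- sac_mask

  # jet entry on the distal ostium and its axis toward the far wall
  entry <- c(config$jet_entry_frac * a, R_v)
  ang <- config$jet_target_angle * pi / 180
  target <- sac_center + R_s * c(cos(ang), sin(ang))
  jet_dir <- (target - entry) / sqrt(sum((target - entry)^2))

  probes <- rbind(
    P1 = entry + 2 * jet_dir,
    P2 = sac_center + (R_s - 1.5) * c(0, 1),
    P3 = c(-a, R_v) + 2 * (sac_center - c(-a, R_v)) /
      sqrt(sum((sac_center - c(-a, R_v))^2))
  )
  colnames(probes) <- c("x", "y")

  geom <- list(config = config, x = x, y = y,
               sac_mask = sac_mask, vessel_mask = vessel_mask,
               lumen_mask = lumen_mask, roi_mask = roi_mask,
               sac_center = sac_center, sac_radius = R_s,
               vessel_halfwidth = R_v, ostium_half = a,
               ostium = rbind(proximal = c(-a, R_v), distal = c(a, R_v)),
               jet_entry = entry, jet_dir = jet_dir, jet_target = target,
               probes = probes)
  class(geom) <- "aneupiv_geometry"
  geom
}

#' @export
print.aneupiv_geometry <- function(x, ...) {
  cfg <- x$config
  cat("Idealized side-wall aneurysm geometry\n")
  cat(sprintf("  sac %g mm on a %g mm vessel (bend %g deg), ostium %g mm\n",
              cfg$sac_diameter, cfg$vessel_diameter, cfg$bend_angle,
              cfg$ostium_width))
  cat(sprintf("  grid %d x %d at %g mm pitch; ROI = sac (%d cells)\n",
              length(x$y), length(x$x), cfg$pitch, sum(x$roi_mask)))
  invisible(x)
}

#' Test whether points lie inside the lumen
#'
#' @param geom An `aneupiv_geometry`.
#' @param x,y Point coordinates (mm), recycled to equal length.
#' @return Logical vector.
#' @export
in_lumen <- function(geom, x, y) {
  R_v <- geom$vessel_halfwidth
  r2 <- (x - geom$sac_center[1])^2 + (y - geom$sac_center[2])^2
  inx <- x >= geom$config$extent_x[1] & x <= geom$config$extent_x[2]
  (abs(y) <= R_v & inx) | (r2 <= geom$sac_radius^2 & y > R_v)
}

#' Points on the no-slip walls
#'
#' Returns `n` points distributed over the wall contour: the sac arc above
#' the ostium plane and the vessel walls (upper wall excluding the ostium
#' opening).
#'
#' @param geom An `aneupiv_geometry`.
#' @param n Number of points.
#' @return An `n x 2` matrix of (x, y) in mm.
#' @export
wall_contour <- function(geom, n = 200) {
  R_s <- geom$sac_radius
  R_v <- geom$vessel_halfwidth
  a <- geom$ostium_half
  C <- geom$sac_center
  n_arc <- ceiling(n * 0.6)
  # sac arc between the two ostium endpoints, going over the dome
  th0 <- atan2(R_v - C[2], a - C[1])         # distal endpoint
  th1 <- atan2(R_v - C[2], -a - C[1])        # proximal endpoint
  th <- seq(th0, th1 + 2 * pi, length.out = n_arc + 2)[2:(n_arc + 1)]
  th <- th %% (2 * pi)
  arc <- cbind(C[1] + R_s * cos(th), C[2] + R_s * sin(th))
  n_rest <- n - n_arc
  xr <- geom$config$extent_x
  xs <- seq(xr[1], xr[2], length.out = ceiling(n_rest / 2))
  lower <- cbind(xs, -R_v)
  xs_up <- xs[abs(xs) > a]
  upper <- cbind(xs_up, R_v)
  pts <- rbind(arc, lower, upper)
  pts[seq_len(min(n, nrow(pts))), , drop = FALSE]
}
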