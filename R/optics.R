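#' Camera and lens specification
#'
#' Bundles the optical parameters of one acquisition camera: focal length
#' \eqn{f}, f-number \eqn{N}, circle of confusion \eqn{c}, the active sensor
#' area and the pixel pitch.  These are the symbols entering the thin-lens
#' depth-of-field model and the first-order field-of-view computations.
#'
#' @param focal_length_mm focal length \eqn{f} in millimetres.
#' @param f_number aperture f-number \eqn{N} (dimensionless).
#' @param circle_of_confusion_mm acceptable circle of confusion \eqn{c} in mm.
#' @param sensor_width_mm,sensor_height_mm active sensor area in mm.  In the
#'   portrait orientation used throughout the package the short side is
#'   horizontal.
#' @param pixel_pitch_um pixel pitch in micrometres.
#' @return An object of class `camera_spec`.
#' @examples
#' camera_spec(4, 2.5, 0.004, 3.7, 4.9, 3.4)
#' @export
camera_spec <- function(focal_length_mm, f_number, circle_of_confusion_mm,
                        sensor_width_mm, sensor_height_mm, pixel_pitch_um = 3.4) {
  vals <- c(focal_length_mm, f_number, circle_of_confusion_mm,
            sensor_width_mm, sensor_height_mm, pixel_pitch_um)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stopf("all camera_spec parameters must be strictly positive and finite")
  structure(list(
    focal_length_mm = focal_length_mm,
    f_number = f_number,
    circle_of_confusion_mm = circle_of_confusion_mm,
    sensor_width_mm = sensor_width_mm,
    sensor_height_mm = sensor_height_mm,
    pixel_pitch_um = pixel_pitch_um,
    sensor_diagonal_mm = sqrt(sensor_width_mm^2 + sensor_height_mm^2)
  ), class = "camera_spec")
}

#' @export
print.camera_spec <- function(x, ...) {
  cat(sprintf("camera_spec: f=%.3g mm  N=%.3g  c=%.4g mm  sensor %.3g x %.3g mm (diag %.3g mm)\n",
              x$focal_length_mm, x$f_number, x$circle_of_confusion_mm,
              x$sensor_width_mm, x$sensor_height_mm, x$sensor_diagonal_mm))
  invisible(x)
}

#' Depth of field of a focused thin lens
#'
#' Computes the hyperfocal distance \eqn{H = f^2/(N c) + f}, the near and far
#' limits of acceptable sharpness
#' \eqn{D_n = s (H - f) / (H + s - 2 f)}, \eqn{D_f = s (H - f) / (H - s)},
#' and the total depth of field \eqn{\Delta = D_f - D_n}, all in millimetres.
#' When the focus distance reaches or exceeds the hyperfocal distance the far
#' limit is unbounded; this is reported through the `far_unbounded` flag
#' rather than an error.
#'
#' @param spec a [camera_spec()].
#' @param focus_distance_mm focus distance \eqn{s} in mm; must exceed the
#'   focal length.
#' @return Object of class `dof_result` with fields `hyperfocal_mm`,
#'   `near_limit_mm`, `far_limit_mm`, `dof_mm`, `focus_distance_mm`,
#'   `far_unbounded`.
#' @examples
#' sp <- camera_spec(4, 2.5, 0.004, 3.7, 4.9)
#' depth_of_field(sp, 120)
#' @export
depth_of_field <- function(spec, focus_distance_mm) {
  stopifnot(inherits(spec, "camera_spec"))
  f <- spec$focal_length_mm
  s <- focus_distance_mm
  if (!is.finite(s) || s <= f)
    stopf("focus distance (%.3g mm) must exceed the focal length (%.3g mm)", s, f)
  H <- f^2 / (spec$f_number * spec$circle_of_confusion_mm) + f
  Dn <- s * (H - f) / (H + s - 2 * f)
  if (s >= H) {
    Df <- Inf
    unbounded <- TRUE
  } else {
    Df <- s * (H - f) / (H - s)
    unbounded <- FALSE
  }
  structure(list(
    hyperfocal_mm = H, near_limit_mm = Dn, far_limit_mm = Df,
    dof_mm = Df - Dn, focus_distance_mm = s, far_unbounded = unbounded
  ), class = "dof_result")
}

#' @export
print.dof_result <- function(x, ...) {
  cat(sprintf("hyperfocal H = %.0f mm\nnear limit Dn = %.0f mm\nfar limit Df = %s\nDoF = %s (s = %.0f mm)\n",
              x$hyperfocal_mm, x$near_limit_mm,
              if (x$far_unbounded) "unbounded" else sprintf("%.0f mm", x$far_limit_mm),
              if (x$far_unbounded) "unbounded" else sprintf("%.1f mm", x$dof_mm),
              x$focus_distance_mm))
  invisible(x)
}

#' Angles of view of a camera
#'
#' Returns the horizontal, vertical and diagonal angles of view in degrees,
#' \eqn{2 \arctan(d / 2f)} for \eqn{d} the short sensor side, the long side
#' and the diagonal respectively (portrait orientation: the short side is
#' horizontal).
#'
#' @param spec a [camera_spec()].
#' @return Named numeric vector `c(horizontal_deg, vertical_deg, diagonal_deg)`.
#' @export
angles_of_view <- function(spec) {
  stopifnot(inherits(spec, "camera_spec"))
  f <- spec$focal_length_mm
  short <- min(spec$sensor_width_mm, spec$sensor_height_mm)
  long <- max(spec$sensor_width_mm, spec$sensor_height_mm)
  ang <- function(d) 2 * atan(d / (2 * f)) * 180 / pi
  c(horizontal_deg = ang(short), vertical_deg = ang(long),
    diagonal_deg = ang(spec$sensor_diagonal_mm))
}

#' First-order field of view at a working distance
#'
#' Pinhole scaling of the sensor extents to object space:
#' \eqn{\mathrm{FoV} = z \cdot d / f} for each sensor dimension \eqn{d}.
#'
#' @param spec a [camera_spec()].
#' @param distance_mm working distance in mm (> 0).
#' @return Named numeric vector `c(horizontal_mm, vertical_mm, diagonal_mm)`.
#' @export
field_of_view_at <- function(spec, distance_mm) {
  stopifnot(inherits(spec, "camera_spec"))
  if (!is.finite(distance_mm) || distance_mm <= 0)
    stopf("distance_mm must be strictly positive")
  f <- spec$focal_length_mm
  short <- min(spec$sensor_width_mm, spec$sensor_height_mm)
  long <- max(spec$sensor_width_mm, spec$sensor_height_mm)
  c(horizontal_mm = distance_mm * short / f,
    vertical_mm = distance_mm * long / f,
    diagonal_mm = distance_mm * spec$sensor_diagonal_mm / f)
}

#' Focal length in pixel units
#'
#' @param spec a [camera_spec()].
#' @return focal length divided by the pixel pitch, in pixels.
#' @export
focal_length_px <- function(spec) {
  stopifnot(inherits(spec, "camera_spec"))
  spec$focal_length_mm / (spec$pixel_pitch_um / 1000)
}
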