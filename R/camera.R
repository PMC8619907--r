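#' Camera model
#'
#' Describes the optical system of a lander camera: sensor pixel dimensions,
#' the full horizontal field of view in air, and the refractive index of the
#' water the housing is immersed in. The in-water field of view is narrower
#' than the in-air one because of refraction at the housing's flat port; see
#' [air_to_water_fov()].
#'
#' @param width_px Horizontal image size in pixels (the `Npixel_x` of the
#'   span-based FOV estimator).
#' @param height_px Vertical image size in pixels.
#' @param fov_air_deg Full horizontal field of view in air, degrees.
#' @param n_water Refractive index of the water, dimensionless. The default
#'   1.34 is standard seawater.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(1600, 1200, fov_air_deg = 82)
#' fov_in_water(cam)
#' @export
camera_model <- function(width_px, height_px, fov_air_deg, n_water = 1.34) {
  stopifnot(
    is.numeric(width_px), length(width_px) == 1, width_px > 0,
    is.numeric(height_px), length(height_px) == 1, height_px > 0,
    is.numeric(fov_air_deg), length(fov_air_deg) == 1,
    fov_air_deg > 0, fov_air_deg < 180,
    is.numeric(n_water), length(n_water) == 1, n_water >= 1
  )
  structure(
    list(
      width_px = as.integer(round(width_px)),
      height_px = as.integer(round(height_px)),
      fov_air_deg = fov_air_deg,
      n_water = n_water
    ),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> %d x %d px (%.2f Mp), FOV %.1f deg in air, %.1f deg in water (n = %.3f)\n",
    x$width_px, x$height_px, megapixels(x$width_px, x$height_px),
    x$fov_air_deg, fov_in_water(x), x$n_water
  ))
  invisible(x)
}

#' In-water field of view of a camera model
#'
#' @param camera A [camera_model()].
#' @return Full horizontal FOV in water, degrees.
#' @export
fov_in_water <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  air_to_water_fov(camera$fov_air_deg, camera$n_water)
}

#' Focal length in pixel units
#'
#' Pinhole focal length implied by the horizontal pixel count and the full
#' horizontal field of view: `f = width_px / (2 tan(fov/2))`.
#'
#' @param camera A [camera_model()].
#' @param medium `"water"` (default; the deployment medium) or `"air"`.
#' @return Focal length in pixels.
#' @export
focal_px <- function(camera, medium = c("water", "air")) {
  stopifnot(inherits(camera, "camera_model"))
  medium <- match.arg(medium)
  fov <- if (medium == "water") fov_in_water(camera) else camera$fov_air_deg
  camera$width_px / (2 * tan(fov * pi / 360))
}

#' Span measurement on a calibration target
#'
#' A single horizontal span seen by the camera: the physical distance between
#' two reference edges of the test pattern, the same distance in image pixels,
#' and the camera-to-pattern distance.
#'
#' @param dx_cm Horizontal physical distance between the two pattern edges, cm.
#' @param dx_pix The same distance measured in the image, pixels.
#' @param distance_cm Camera-to-pattern distance, cm.
#' @return An object of class `span_measurement`.
#' @export
span_measurement <- function(dx_cm, dx_pix, distance_cm) {
  stopifnot(
    is.numeric(dx_cm), length(dx_cm) == 1, dx_cm >= 0,
    is.numeric(dx_pix), length(dx_pix) == 1,
    is.numeric(distance_cm), length(distance_cm) == 1
  )
  if (!(dx_pix > 0)) {
    stop("invalid span measurement: dx_pix must be > 0", call. = FALSE)
  }
  if (!(distance_cm > 0)) {
    stop("invalid span measurement: distance_cm must be > 0", call. = FALSE)
  }
  structure(
    list(dx_cm = dx_cm, dx_pix = dx_pix, distance_cm = distance_cm),
    class = "span_measurement"
  )
}

#' @export
print.span_measurement <- function(x, ...) {
  cat(sprintf(
    "<span_measurement> %.2f cm == %.2f px at D = %.1f cm\n",
    x$dx_cm, x$dx_pix, x$distance_cm
  ))
  invisible(x)
}

#' Field of view from a measured span
#'
#' Estimates the full horizontal field of view from a single span measured on
#' a flat target at known distance:
#' \deqn{\theta = 2 \arctan\!\left(\frac{N_x \, dx_{cm}}{2 \, D \, dx_{pix}}\right)}
#' where `N_x` is the horizontal image size in pixels, `dx_cm` the physical
#' span, `dx_pix` the same span in pixels and `D` the camera-to-target
#' distance in cm.
#'
#' @param camera A [camera_model()] (only `width_px` is used).
#' @param span A [span_measurement()].
#' @return FOV in degrees, in `[0, 180)`.
#' @examples
#' cam <- camera_model(1600, 1200, 82)
#' fov_from_span(cam, span_measurement(200, 1600, 173.2))
#' @export
fov_from_span <- function(camera, span) {
  stopifnot(inherits(camera, "camera_model"), inherits(span, "span_measurement"))
  2 * atan(camera$width_px * span$dx_cm / (2 * span$distance_cm * span$dx_pix)) *
    180 / pi
}

#' Flat-port refraction conversion of the field of view
#'
#' A flat housing port bends rays at the water/air interface following
#' Snell's law; the half field of view in water `w/2` and in air `a/2` are
#' related by `sin(a/2) = n sin(w/2)`. `air_to_water_fov()` narrows an in-air
#' FOV to its in-water equivalent; `water_to_air_fov()` is the inverse. Port
#' thickness is neglected (thin flat port).
#'
#' @param fov_air_deg Full FOV in air, degrees, in `[0, 180)`.
#' @param fov_water_deg Full FOV in water, degrees, in `[0, 180)`.
#' @param n_water Refractive index of water (>= 1); default 1.34 (seawater).
#' @return Converted full FOV in degrees.
#' @examples
#' air_to_water_fov(82)          # ~58.6, rounds to 59
#' water_to_air_fov(60)          # ~84.1, rounds to 84
#' @export
air_to_water_fov <- function(fov_air_deg, n_water = 1.34) {
  stopifnot(all(fov_air_deg >= 0), all(fov_air_deg < 180), n_water >= 1)
  2 * asin(sin(fov_air_deg * pi / 360) / n_water) * 180 / pi
}

#' @rdname air_to_water_fov
#' @export
water_to_air_fov <- function(fov_water_deg, n_water = 1.34) {
  stopifnot(all(fov_water_deg >= 0), all(fov_water_deg < 180), n_water >= 1)
  s <- n_water * sin(fov_water_deg * pi / 360)
  if (any(s > 1)) {
    stop("total internal reflection: n * sin(fov/2) > 1; no in-air equivalent",
         call. = FALSE)
  }
  2 * asin(s) * 180 / pi
}

#' Sensor size in megapixels
#'
#' @param width_px,height_px Image dimensions in pixels (non-negative).
#' @return Megapixels, rounded to two decimals (the convention used in
#'   format names such as UXGA 1.92 Mp, Full HD 2.07 Mp).
#' @export
megapixels <- function(width_px, height_px) {
  stopifnot(all(width_px >= 0), all(height_px >= 0))
  round(width_px * height_px / 1e6, 2)
}
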