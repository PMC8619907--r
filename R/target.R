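#' Physical calibration-target description
#'
#' A flat black-and-white grid pattern plus a colour chart, as used in a
#' controlled-pool calibration: grid nodes are the intersections of evenly
#' spaced dark lines; the two outermost vertical lines are the reference
#' edges whose physical separation (`edge_span_cm`) feeds the span-based FOV
#' estimator. Colour patches carry known reference RGB values.
#'
#' Target-plane coordinates are in cm, origin at the grid center, x
#' rightward, y downward (matching image raster orientation).
#'
#' @param node_pitch_cm Spacing between grid lines, cm (> 0).
#' @param n_rows,n_cols Number of grid lines per direction (>= 2); nodes are
#'   their `n_rows x n_cols` intersections.
#' @param edge_span_cm Horizontal distance between the two reference edges;
#'   defaults to the outer-line separation `(n_cols - 1) * node_pitch_cm`.
#' @param line_width_cm Drawn line width, cm; default 5% of the pitch.
#' @param patches Colour-chart layout: a data frame with columns `patch_id`,
#'   `r`, `g`, `b` (reference values, 0-255), `x_cm`, `y_cm` (patch center),
#'   `w_cm`, `h_cm`. Default [default_color_chart()] placed below the grid.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(node_pitch_cm, n_rows = 7, n_cols = 9,
                        edge_span_cm = (n_cols - 1) * node_pitch_cm,
                        line_width_cm = 0.05 * node_pitch_cm,
                        patches = default_color_chart(node_pitch_cm, n_rows, n_cols)) {
  stopifnot(
    node_pitch_cm > 0, n_rows >= 2, n_cols >= 2,
    edge_span_cm > 0, line_width_cm > 0
  )
  if (!is.null(patches)) {
    need <- c("patch_id", "r", "g", "b", "x_cm", "y_cm", "w_cm", "h_cm")
    stopifnot(is.data.frame(patches), all(need %in% names(patches)))
    stopifnot(all(patches[, c("r", "g", "b")] >= 0),
              all(patches[, c("r", "g", "b")] <= 255))
  }
  structure(
    list(
      node_pitch_cm = node_pitch_cm,
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      edge_span_cm = edge_span_cm, line_width_cm = line_width_cm,
      patches = patches
    ),
    class = "target_spec"
  )
}

#' @export
print.target_spec <- function(x, ...) {
  cat(sprintf(
    "<target_spec> %dx%d grid, pitch %.2f cm, edge span %.1f cm, %d colour patches\n",
    x$n_rows, x$n_cols, x$node_pitch_cm, x$edge_span_cm,
    if (is.null(x$patches)) 0L else nrow(x$patches)
  ))
  invisible(x)
}

#' Default colour chart layout
#'
#' Six patches (red, green, blue, yellow, mid-grey, white) in one row below
#' the grid. Reference values are arbitrary but span the channels so that
#' per-channel attenuation is identifiable.
#'
#' @param node_pitch_cm,n_rows,n_cols Grid geometry the chart is sized to.
#' @return Patch layout data frame (see [target_spec()]).
#' @export
default_color_chart <- function(node_pitch_cm, n_rows = 7, n_cols = 9) {
  cols <- rbind(
    red = c(220, 50, 40), green = c(60, 200, 70), blue = c(50, 80, 220),
    yellow = c(230, 215, 60), grey = c(128, 128, 128), white = c(245, 245, 245)
  )
  n <- nrow(cols)
  grid_w <- (n_cols - 1) * node_pitch_cm
  grid_h <- (n_rows - 1) * node_pitch_cm
  size <- grid_w / 10
  xs <- (seq_len(n) - (n + 1) / 2) * (size * 1.3)
  data.frame(
    patch_id = rownames(cols),
    r = cols[, 1], g = cols[, 2], b = cols[, 3],
    x_cm = xs,
    y_cm = grid_h / 2 + 0.75 * node_pitch_cm + size / 2,
    w_cm = size, h_cm = size,
    row.names = NULL
  )
}

#' Per-channel exponential attenuation of colour with distance
#'
#' Beer-Lambert attenuation of each RGB channel over the optical path from
#' target to camera: channel value at distance `D` (m) is
#' `reference * exp(-k_c D)`. Defaults are seawater-like, with red absorbed
#' fastest (long wavelengths attenuate first in water).
#'
#' @param k_r,k_g,k_b Attenuation coefficients per channel, m^-1 (>= 0).
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(k_r = 0.6, k_g = 0.15, k_b = 0.08) {
  stopifnot(k_r >= 0, k_g >= 0, k_b >= 0)
  structure(list(k = c(r = k_r, g = k_g, b = k_b)), class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat(sprintf("<attenuation_model> k = (%.3f, %.3f, %.3f) m^-1 (r, g, b)\n",
              x$k["r"], x$k["g"], x$k["b"]))
  invisible(x)
}

#' Attenuate a reference colour over a water path
#'
#' @param reference_rgb Numeric triplet (or n x 3 matrix) of channel values
#'   in 0-255.
#' @param attenuation An [attenuation_model()].
#' @param distance_m Optical path length, m (>= 0).
#' @return Attenuated values, clipped to `[0, 255]`, same shape.
#' @examples
#' attenuate_color(c(200, 200, 200), attenuation_model(0.5, 0.1, 0.05), 3)
#' @export
attenuate_color <- function(reference_rgb, attenuation, distance_m) {
  stopifnot(inherits(attenuation, "attenuation_model"), distance_m >= 0)
  m <- if (is.matrix(reference_rgb)) reference_rgb else
    matrix(reference_rgb, ncol = 3)
  stopifnot(ncol(m) == 3)
  out <- sweep(m, 2, exp(-attenuation$k * distance_m), `*`)
  out <- pmin(pmax(out, 0), 255)
  if (is.matrix(reference_rgb)) out else drop(out)
}

#' Full generative description of one pool calibration shot
#'
#' Bundles everything needed to render (and later analyse) a synthetic image
#' of the calibration target: the camera, the target geometry, the
#' camera-to-target distance, the lens distortion, the water colour
#' attenuation, and additive pixel noise.
#'
#' @param camera A [camera_model()].
#' @param target A [target_spec()]; default [target_for_distance()], which
#'   scales the pattern so the grid fills ~70% of the frame width at
#'   `distance_cm` (emulating the use of several pattern sizes at the
#'   different pool distances).
#' @param distance_cm Camera-to-target distance, cm (> 0).
#' @param distortion A [distortion_model()]; default coefficient 1.3e-4
#'   pix^-1, a moderate pincushion typical of a flat-port housing.
#' @param attenuation An [attenuation_model()].
#' @param noise_sigma Additive Gaussian pixel noise sd, 0-255 scale (>= 0).
#' @param seed Integer RNG seed; required when `noise_sigma > 0`.
#' @param background_rgb,line_rgb Background and grid-line colours (0-255
#'   triplets) before attenuation.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(camera, distance_cm,
                       target = target_for_distance(distance_cm, camera),
                       distortion = distortion_model(1.3e-4),
                       attenuation = attenuation_model(),
                       noise_sigma = 1, seed = 1L,
                       background_rgb = c(235, 235, 235),
                       line_rgb = c(25, 25, 25)) {
  stopifnot(inherits(camera, "camera_model"))
  if (!(distance_cm > 0)) stop("distance_cm must be > 0", call. = FALSE)
  stopifnot(
    inherits(target, "target_spec"),
    inherits(distortion, "distortion_model"),
    inherits(attenuation, "attenuation_model"),
    noise_sigma >= 0
  )
  if (noise_sigma > 0 && (is.null(seed) || is.na(seed))) {
    stop("a seed must be set whenever noise_sigma > 0", call. = FALSE)
  }
  structure(
    list(
      camera = camera, target = target, distance_cm = distance_cm,
      distortion = distortion, attenuation = attenuation,
      noise_sigma = noise_sigma, seed = if (is.null(seed)) NULL else as.integer(seed),
      background_rgb = background_rgb, line_rgb = line_rgb
    ),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> D = %.0f cm, d = %.3g (%s), noise sd %.1f, seed %s\n",
    x$distance_cm, x$distortion$d, x$distortion$form, x$noise_sigma,
    if (is.null(x$seed)) "unset" else x$seed
  ))
  invisible(x)
}

#' Scale a default target to a capture distance
#'
#' Chooses the grid pitch so that the grid spans a fixed fraction of the
#' frame width at the given distance — the practice of using larger pattern
#' prints at larger distances, keeping the grid's pixel footprint constant.
#' The default 7 x 9 grid at 60% frame width leaves room below the grid for
#' the colour chart and a margin for pincushion displacement inside a 4:3
#' frame.
#'
#' @param distance_cm Camera-to-target distance, cm.
#' @param camera A [camera_model()].
#' @param fill_frac Fraction of the frame width the grid spans (default 0.6).
#' @param n_rows,n_cols Grid line counts.
#' @return A [target_spec()].
#' @export
target_for_distance <- function(distance_cm, camera, fill_frac = 0.6,
                                n_rows = 7, n_cols = 9) {
  f <- focal_px(camera)
  pitch_cm <- fill_frac * camera$width_px * distance_cm / f / (n_cols - 1)
  target_spec(node_pitch_cm = pitch_cm, n_rows = n_rows, n_cols = n_cols)
}
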