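# Synthetic rendering of pool calibration shots: pinhole projection of the
# target, distortion, per-channel water attenuation, additive noise.

clamp <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

grid_line_positions_cm <- function(target) {
  list(
    x = (seq_len(target$n_cols) - (target$n_cols + 1) / 2) * target$node_pitch_cm,
    y = (seq_len(target$n_rows) - (target$n_rows + 1) / 2) * target$node_pitch_cm
  )
}

#' Project the calibration target through the camera
#'
#' Pinhole projection of the grid nodes and colour patches onto the sensor at
#' the scene's capture distance, followed by the scene's lens distortion.
#' The focal length in pixels is `width_px / (2 tan(fov_water/2))`, using the
#' camera's in-water field of view. Nodes projecting outside the frame are
#' dropped and counted.
#'
#' @param scene A [scene_spec()].
#' @return A list with components:
#'   * `nodes`: [node_set()] of visible nodes (ideal = undistorted pinhole
#'     projection, observed = after distortion), center-relative pixels;
#'   * `n_dropped`: nodes outside the frame;
#'   * `patches`: patch layout in pixels (`cx`, `cy`, `w`, `h`, ideal
#'     positions) joined with the reference RGB;
#'   * `span`: the ground-truth [span_measurement()] between the reference
#'     edges (undistorted pixel span);
#'   * `focal_px`: the focal length used.
#' @export
project_target <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  cam <- scene$camera
  f <- focal_px(cam)
  D <- scene$distance_cm
  pos <- grid_line_positions_cm(scene$target)
  g <- expand.grid(y_cm = pos$y, x_cm = pos$x) # row-major within columns of x
  g <- g[order(g$y_cm, g$x_cm), ]
  ideal <- cbind(x = g$x_cm * f / D, y = g$y_cm * f / D)
  observed <- apply_distortion(ideal, scene$distortion)
  half_w <- cam$width_px / 2
  half_h <- cam$height_px / 2
  vis <- abs(observed[, 1]) < half_w & abs(observed[, 2]) < half_h
  if (!any(vis)) stop("target entirely outside the field of view", call. = FALSE)
  n_dropped <- sum(!vis)
  patches <- scene$target$patches
  if (!is.null(patches)) {
    ctr_ideal <- cbind(patches$x_cm, patches$y_cm) * f / D
    ctr_obs <- apply_distortion(ctr_ideal, scene$distortion)
    patches <- cbind(
      patches,
      # cx/cy are where the patch appears in the (distorted) image; the
      # ideal (undistorted) centers are kept alongside
      cx = ctr_obs[, 1], cy = ctr_obs[, 2],
      cx_ideal = ctr_ideal[, 1], cy_ideal = ctr_ideal[, 2],
      w = patches$w_cm * f / D, h = patches$h_cm * f / D
    )
  }
  list(
    nodes = node_set(ideal[vis, , drop = FALSE], observed[vis, , drop = FALSE]),
    n_dropped = n_dropped,
    patches = patches,
    span = span_measurement(scene$target$edge_span_cm,
                            scene$target$edge_span_cm * f / D, D),
    focal_px = f
  )
}

#' Render a synthetic calibration-target image
#'
#' Draws the grid (anti-aliased dark lines on a light background) and the
#' colour patches as seen through the scene's camera: pinhole projection at
#' the capture distance, lens distortion, per-channel Beer-Lambert
#' attenuation over the water path, then additive Gaussian pixel noise
#' (seeded; identical seeds give identical images). Values are 0-255 doubles;
#' quantization to 8 bits happens only on [write_image()].
#'
#' The distorted geometry is rendered by inverse mapping: each output pixel
#' is mapped back through the distortion inverse to its position on the
#' (flat) target plane, where grid-line and patch coverage are evaluated
#' analytically with a one-pixel anti-aliasing ramp.
#'
#' @param scene A [scene_spec()].
#' @return An object of class `scene_render`: list with `image`
#'   (`height x width x 3` array, 0-255) and `truth` (ground-truth sidecar:
#'   the [project_target()] geometry plus all generative parameters and the
#'   attenuated patch colours).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  cam <- scene$camera
  w <- cam$width_px; h <- cam$height_px
  proj <- project_target(scene)
  f <- proj$focal_px
  D <- scene$distance_cm
  px_per_cm <- f / D

  xs <- rep(0:(w - 1) - w / 2, each = h)
  ys <- rep(0:(h - 1) - h / 2, times = w)
  if (scene$distortion$d != 0) {
    real <- undistort_points(cbind(xs, ys), scene$distortion)
  } else {
    real <- cbind(xs, ys)
  }
  x_cm <- real[, 1] / px_per_cm
  y_cm <- real[, 2] / px_per_cm

  tg <- scene$target
  pos <- grid_line_positions_cm(tg)
  hw_px <- max(tg$line_width_cm / 2 * px_per_cm, 0.5)
  # lines overhang the outer nodes by a quarter pitch so that edge nodes sit
  # on full crossings (keeps their centroid refinement unbiased)
  overhang <- 0.25 * tg$node_pitch_cm
  half_gw <- (tg$n_cols - 1) / 2 * tg$node_pitch_cm + overhang
  half_gh <- (tg$n_rows - 1) / 2 * tg$node_pitch_cm + overhang

  nearest_line_dist <- function(v, line_pos) {
    idx <- pmin(pmax(round(v / tg$node_pitch_cm + (length(line_pos) + 1) / 2), 1),
                length(line_pos))
    abs(v - line_pos[idx])
  }
  dvx <- nearest_line_dist(x_cm, pos$x) * px_per_cm
  dvy <- nearest_line_dist(y_cm, pos$y) * px_per_cm
  cov_v <- clamp(hw_px + 0.5 - dvx, 0, 1) * (abs(y_cm) <= half_gh)
  cov_h <- clamp(hw_px + 0.5 - dvy, 0, 1) * (abs(x_cm) <= half_gw)
  cov <- pmax(cov_v, cov_h)

  att <- exp(-scene$attenuation$k * (D / 100))
  img <- array(0, dim = c(h, w, 3))
  channel <- vector("list", 3)
  for (ch in 1:3) {
    channel[[ch]] <- scene$background_rgb[ch] +
      (scene$line_rgb[ch] - scene$background_rgb[ch]) * cov
  }
  patches <- proj$patches
  patch_rgb_att <- NULL
  if (!is.null(patches) && nrow(patches)) {
    ref <- as.matrix(patches[, c("r", "g", "b")])
    patch_rgb_att <- attenuate_color(ref, scene$attenuation, D / 100)
    for (i in seq_len(nrow(patches))) {
      # work only on the pixel subrectangle covering the distorted patch
      corners <- as.matrix(expand.grid(
        x = patches$cx_ideal[i] + c(-1, 1) * (patches$w[i] / 2 + 2),
        y = patches$cy_ideal[i] + c(-1, 1) * (patches$h[i] / 2 + 2)
      ))
      cd <- apply_distortion(corners, scene$distortion)
      jr <- clamp(floor(min(cd[, 1]) + w / 2):ceiling(max(cd[, 1]) + w / 2) + 1,
                  1, w)
      ir <- clamp(floor(min(cd[, 2]) + h / 2):ceiling(max(cd[, 2]) + h / 2) + 1,
                  1, h)
      idx <- as.vector(outer(unique(ir), (unique(jr) - 1) * h, `+`))
      covx <- clamp((patches$w_cm[i] / 2 - abs(x_cm[idx] - patches$x_cm[i])) *
                      px_per_cm + 0.5, 0, 1)
      covy <- clamp((patches$h_cm[i] / 2 - abs(y_cm[idx] - patches$y_cm[i])) *
                      px_per_cm + 0.5, 0, 1)
      covp <- covx * covy
      for (ch in 1:3) {
        # patch reference colour is attenuated with the rest of the scene below
        channel[[ch]][idx] <- channel[[ch]][idx] * (1 - covp) + ref[i, ch] * covp
      }
    }
  }
  for (ch in 1:3) {
    img[, , ch] <- matrix(channel[[ch]] * att[ch], nrow = h)
  }
  if (scene$noise_sigma > 0) {
    img <- with_seed(scene$seed,
                     img + array(stats::rnorm(length(img), 0, scene$noise_sigma),
                                 dim = dim(img)))
  }
  img <- clamp(img, 0, 255)

  truth <- list(
    nodes = proj$nodes,
    n_dropped = proj$n_dropped,
    patches = patches,
    patch_rgb_attenuated = patch_rgb_att,
    span = proj$span,
    focal_px = f,
    fov_water_deg = fov_in_water(cam),
    params = list(
      width_px = w, height_px = h, fov_air_deg = cam$fov_air_deg,
      n_water = cam$n_water, distance_cm = D,
      d = scene$distortion$d, form = scene$distortion$form,
      k = as.list(scene$attenuation$k),
      noise_sigma = scene$noise_sigma, seed = scene$seed
    )
  )
  structure(list(image = img, truth = truth), class = "scene_render")
}

#' @export
print.scene_render <- function(x, ...) {
  dm <- dim(x$image)
  cat(sprintf("<scene_render> %d x %d px, D = %.0f cm, %d visible nodes\n",
              dm[2], dm[1], x$truth$params$distance_cm, nrow(x$truth$nodes$ideal)))
  invisible(x)
}

#' Read and write raster images
#'
#' Images are `height x width x channels` numeric arrays on a 0-255 scale.
#' Format follows the file extension: `.png` (via \pkg{png}) or
#' `.tif`/`.tiff` (via \pkg{tiff}, if installed).
#'
#' @param path File path.
#' @param image Numeric matrix or array, values in 0-255.
#' @return `read_image` returns the image array; `write_image` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  img * 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  scaled <- pmin(pmax(image / 255, 0), 1)
  switch(ext,
    png = png::writePNG(scaled, target = path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::writeTIFF(scaled, path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
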