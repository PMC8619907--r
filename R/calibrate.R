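# End-to-end calibration of a target image: detect -> match -> fit
# distortion -> undistort -> span -> FOV, plus the colour-series analysis
# and fixture generation.

#' Calibrate from one target image
#'
#' Runs the full optical-calibration chain on a grid-target image taken at a
#' known distance: sub-pixel node detection, matching against the projected
#' ideal grid, least-squares distortion fitting, distortion correction of
#' the node positions, reference-edge span measurement, and the span-based
#' FOV estimate.
#'
#' @param image Image array (0-255) or a path readable by [read_image()].
#' @param target A [target_spec()].
#' @param camera A [camera_model()].
#' @param distance_cm Camera-to-target distance, cm.
#' @param form Distortion form passed to [fit_distortion()].
#' @return An object of class `calibration` with the FOV estimate
#'   (`fov_deg`), the `distortion_fit`, the corrected [span_measurement()],
#'   the matched [node_set()], and the inputs' summary.
#' @export
calibrate_image <- function(image, target, camera, distance_cm,
                            form = c("radial", "literal")) {
  form <- match.arg(form)
  if (is.character(image)) image <- read_image(image)
  detected <- detect_nodes(image)
  nodes <- match_nodes(detected, target, camera, distance_cm)
  dfit <- fit_distortion(nodes, form = form)
  corrected <- node_set(nodes$ideal, undistort_points(nodes$observed, dfit$model))
  span <- measure_span(corrected, target, distance_cm)
  fov <- fov_from_span(camera, span)
  structure(
    list(
      fov_deg = fov, distortion = dfit, span = span,
      nodes = nodes, corrected_nodes = corrected,
      camera = camera, target = target, distance_cm = distance_cm,
      n_detected = nrow(detected),
      n_unmatched = attr(nodes, "n_unmatched")
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> D = %.0f cm, %d/%d nodes matched\n",
              x$distance_cm, nrow(x$nodes$ideal), x$n_detected))
  cat(sprintf("  FOV (distortion-corrected span): %.2f deg\n", x$fov_deg))
  cat(sprintf("  distortion: d = %.6g pix^-1 (%s), RMS %.3g px\n",
              x$distortion$d, x$distortion$label, x$distortion$rms))
  invisible(x)
}

#' @export
summary.calibration <- function(object, ...) {
  print(object)
  cat(sprintf("  span: %.1f cm == %.2f px; in-air FOV equivalent: %.2f deg\n",
              object$span$dx_cm, object$span$dx_pix,
              water_to_air_fov(object$fov_deg, object$camera$n_water)))
  invisible(object)
}

#' Colour analysis over a distance series
#'
#' Extracts chart-patch measurements from each image of a distance series
#' and fits the per-channel attenuation coefficients.
#'
#' @param images List of image arrays (or paths), one per distance.
#' @param patch_layouts List of pixel-space patch layouts (from
#'   [project_target()]), matched to `images`.
#' @param distances_m Numeric vector of capture distances, m.
#' @param floor Measurement floor passed to [fit_attenuation()].
#' @return An `attenuation_fit` with the pooled measurement table attached
#'   as `measurements`.
#' @export
analyze_color_series <- function(images, patch_layouts, distances_m,
                                 floor = 5) {
  stopifnot(length(images) == length(distances_m),
            length(patch_layouts) == length(distances_m))
  tabs <- mapply(function(img, lay, D) {
    if (is.character(img)) img <- read_image(img)
    chart_measurements(img, lay, D)
  }, images, patch_layouts, distances_m, SIMPLIFY = FALSE)
  tab <- do.call(rbind, tabs)
  fit <- fit_attenuation(tab, floor = floor)
  fit$measurements <- tab
  fit
}

#' Simulate and analyse a full pool calibration session
#'
#' Renders the standard distance series (default 1-6 m) of synthetic target
#' shots with known ground truth and runs the full analysis on each:
#' calibration (FOV + distortion) per image and one pooled attenuation fit,
#' returning estimates next to the truth.
#'
#' @param camera A [camera_model()].
#' @param distances_m Capture distances in meters (default `1:6`).
#' @param d True distortion coefficient (default 1.3e-4 pix^-1).
#' @param attenuation True [attenuation_model()].
#' @param noise_sigma Pixel noise sd (default 1).
#' @param seed Base RNG seed; image `i` uses `seed + i`.
#' @param form Distortion form.
#' @return List with `per_image` (data frame of per-distance truth and
#'   estimates), `attenuation` (`attenuation_fit`), `truth` (list of true
#'   parameters) and `calibrations` (list of `calibration` objects).
#' @export
pool_experiment <- function(camera = camera_model(1600, 1200, 82),
                            distances_m = 1:6, d = 1.3e-4,
                            attenuation = attenuation_model(),
                            noise_sigma = 1, seed = 1L,
                            form = c("radial", "literal")) {
  form <- match.arg(form)
  fov_true <- fov_in_water(camera)
  cals <- vector("list", length(distances_m))
  imgs <- vector("list", length(distances_m))
  lays <- vector("list", length(distances_m))
  for (i in seq_along(distances_m)) {
    D <- distances_m[i] * 100
    scene <- scene_spec(camera, D,
                        distortion = distortion_model(d, form),
                        attenuation = attenuation,
                        noise_sigma = noise_sigma, seed = seed + i)
    ren <- render_scene(scene)
    cals[[i]] <- calibrate_image(ren$image, scene$target, camera, D,
                                 form = form)
    imgs[[i]] <- ren$image
    lays[[i]] <- ren$truth$patches
  }
  afit <- analyze_color_series(imgs, lays, distances_m)
  per_image <- data.frame(
    distance_m = distances_m,
    fov_true = fov_true,
    fov_est = vapply(cals, `[[`, numeric(1), "fov_deg"),
    d_true = d,
    d_est = vapply(cals, function(c) c$distortion$d, numeric(1))
  )
  list(
    per_image = per_image,
    attenuation = afit,
    truth = list(fov_water_deg = fov_true, d = d, k = attenuation$k,
                 noise_sigma = noise_sigma, seed = seed),
    calibrations = cals
  )
}

#' Generate the standard fixture series
#'
#' Writes the synthetic pool series (default 1-6 m) as PNG images with JSON
#' ground-truth sidecars: per image the visible node set, the patch layout
#' with reference and attenuated colours, the true span, and every
#' generative parameter (including the seed).
#'
#' @param dir Output directory (created if missing).
#' @param camera A [camera_model()].
#' @param distances_m Distances in meters.
#' @param d True distortion coefficient.
#' @param attenuation True [attenuation_model()].
#' @param noise_sigma Pixel noise sd.
#' @param seed Base seed; image `i` uses `seed + i`.
#' @return Data frame with columns `distance_m`, `image`, `sidecar`.
#' @export
make_fixtures <- function(dir, camera = camera_model(1600, 1200, 82),
                          distances_m = 1:6, d = 1.3e-4,
                          attenuation = attenuation_model(),
                          noise_sigma = 1, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- data.frame(distance_m = distances_m,
                    image = character(length(distances_m)),
                    sidecar = character(length(distances_m)))
  for (i in seq_along(distances_m)) {
    D <- distances_m[i] * 100
    scene <- scene_spec(camera, D,
                        distortion = distortion_model(d),
                        attenuation = attenuation,
                        noise_sigma = noise_sigma, seed = seed + i)
    ren <- render_scene(scene)
    stem <- sprintf("target_%02dm", distances_m[i])
    img_path <- file.path(dir, paste0(stem, ".png"))
    sc_path <- file.path(dir, paste0(stem, ".json"))
    write_image(ren$image, img_path)
    truth <- ren$truth
    sidecar <- list(
      params = truth$params,
      fov_water_deg = truth$fov_water_deg,
      focal_px = truth$focal_px,
      span = unclass(truth$span),
      nodes = list(ideal = unname(truth$nodes$ideal),
                   observed = unname(truth$nodes$observed)),
      patches = truth$patches,
      patch_rgb_attenuated = truth$patch_rgb_attenuated
    )
    jsonlite::write_json(sidecar, sc_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    out$image[i] <- img_path
    out$sidecar[i] <- sc_path
  }
  out
}

#' Read a fixture ground-truth sidecar
#'
#' @param path Sidecar JSON path.
#' @return The sidecar list with `nodes` restored to a [node_set()] and
#'   `patches` to a data frame.
#' @export
read_sidecar <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc$nodes <- node_set(sc$nodes$ideal, sc$nodes$observed)
  sc$patches <- as.data.frame(sc$patches)
  sc
}
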