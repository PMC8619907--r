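# YAML/JSON configuration for cameras, targets and scenes. Angles are in
# degrees and physical distances in cm throughout config files.

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
}

#' Read a camera description from a config file
#'
#' YAML or JSON with fields `width_px`, `height_px`, `fov_air_deg` and
#' optionally `n_water`.
#'
#' @param path Config file path (`.yaml`/`.yml`/`.json`).
#' @return A [camera_model()].
#' @export
read_camera_config <- function(path) {
  cfg <- read_config_file(path)
  need <- c("width_px", "height_px", "fov_air_deg")
  if (!all(need %in% names(cfg))) {
    stop("camera config must define ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  camera_model(cfg$width_px, cfg$height_px, cfg$fov_air_deg,
               n_water = if (is.null(cfg$n_water)) 1.34 else cfg$n_water)
}

#' Read a full scene description from a config file
#'
#' YAML or JSON with a `camera` block (see [read_camera_config()]), a
#' `distance_cm`, and optional `target` (`node_pitch_cm`, `n_rows`,
#' `n_cols`), `distortion` (`d`, `form`), `attenuation` (`k_r`, `k_g`,
#' `k_b`), `noise_sigma` and `seed` blocks. Omitted blocks use the package
#' defaults.
#'
#' @param path Config file path.
#' @return A [scene_spec()].
#' @export
read_scene_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$camera) || is.null(cfg$distance_cm)) {
    stop("scene config must define 'camera' and 'distance_cm'", call. = FALSE)
  }
  cam <- camera_model(cfg$camera$width_px, cfg$camera$height_px,
                      cfg$camera$fov_air_deg,
                      n_water = if (is.null(cfg$camera$n_water)) 1.34
                                else cfg$camera$n_water)
  target <- if (is.null(cfg$target)) {
    target_for_distance(cfg$distance_cm, cam)
  } else {
    target_spec(cfg$target$node_pitch_cm,
                n_rows = if (is.null(cfg$target$n_rows)) 9 else cfg$target$n_rows,
                n_cols = if (is.null(cfg$target$n_cols)) 9 else cfg$target$n_cols)
  }
  distortion <- if (is.null(cfg$distortion)) distortion_model(1.3e-4) else
    distortion_model(cfg$distortion$d,
                     form = if (is.null(cfg$distortion$form)) "radial"
                            else cfg$distortion$form)
  attenuation <- if (is.null(cfg$attenuation)) attenuation_model() else
    attenuation_model(cfg$attenuation$k_r, cfg$attenuation$k_g,
                      cfg$attenuation$k_b)
  scene_spec(cam, cfg$distance_cm, target = target, distortion = distortion,
             attenuation = attenuation,
             noise_sigma = if (is.null(cfg$noise_sigma)) 1 else cfg$noise_sigma,
             seed = if (is.null(cfg$seed)) 1L else cfg$seed)
}
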