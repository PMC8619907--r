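# Shared fixture builders. Unit tests mostly use a reduced-resolution camera
# (same optics, 800 x 600) so renders stay fast; end-to-end and acceptance
# checks use the full 1600 x 1200 format.

uxga_camera <- function() camera_model(1600, 1200, fov_air_deg = 82)
small_camera <- function() camera_model(800, 600, fov_air_deg = 82)

small_scene <- function(distance_cm = 300, d = 1.3e-4, noise_sigma = 0,
                        seed = 1L, camera = small_camera(),
                        attenuation = attenuation_model(), form = "radial") {
  scene_spec(camera, distance_cm,
             distortion = distortion_model(d, form),
             attenuation = attenuation,
             noise_sigma = noise_sigma, seed = seed)
}

# regular 9 x 9 node grid spanning ~1000 px, center-relative
regular_grid <- function(span = 1000, n = 9) {
  s <- seq(-span / 2, span / 2, length.out = n)
  as.matrix(expand.grid(x = s, y = s))
}

# brute-force 1-D grid-search oracle for the distortion coefficient
grid_search_d <- function(nodes, form, lo, hi, step = 1e-7) {
  ds <- seq(lo, hi, by = step)
  sse <- vapply(ds, function(d) {
    pred <- apply_distortion(nodes$ideal, distortion_model(d, form))
    sum((nodes$observed - pred)^2)
  }, numeric(1))
  ds[which.min(sse)]
}

# brute-force 1-D grid-search oracle for one attenuation coefficient
grid_search_k <- function(D, y, lo = 0, hi = 1, step = 1e-4) {
  ks <- seq(lo, hi, by = step)
  sse <- vapply(ks, function(k) sum((y - k * D)^2), numeric(1))
  ks[which.min(sse)]
}

# nearest-match error of each reference point to a detected set
match_errors <- function(detected, reference) {
  d2 <- outer(reference[, 1], detected[, 1], `-`)^2 +
    outer(reference[, 2], detected[, 2], `-`)^2
  sqrt(apply(d2, 1, min))
}
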