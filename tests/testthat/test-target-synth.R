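# Synthetic scene generator: projection self-consistency, colour
# attenuation, rendering determinism and ground truth.

test_that("projected ground-truth span returns the configured FOV", {
  cam <- small_camera()
  for (D in c(100, 250, 600)) {
    scene <- small_scene(distance_cm = D, d = 0, noise_sigma = 0)
    proj <- project_target(scene)
    expect_equal(fov_from_span(cam, proj$span), fov_in_water(cam),
                 tolerance = 1e-9)
  }
})

test_that("pinhole scaling: doubling the distance halves the pixel span", {
  s1 <- small_scene(distance_cm = 150, d = 0, noise_sigma = 0,
                    camera = small_camera())
  # same physical target at twice the distance
  s2 <- scene_spec(small_camera(), 300, target = s1$target,
                   distortion = distortion_model(0), noise_sigma = 0)
  p1 <- project_target(s1)
  p2 <- project_target(s2)
  expect_equal(p2$span$dx_pix, p1$span$dx_pix / 2, tolerance = 1e-9)
})

test_that("fitting the emitted node set recovers the scene coefficient", {
  scene <- small_scene(distance_cm = 300, d = 1.3e-4, noise_sigma = 0)
  proj <- project_target(scene)
  fit <- fit_distortion(proj$nodes)
  expect_equal(fit$d, 1.3e-4, tolerance = 1e-12)
})

test_that("nodes outside the frame are dropped; an invisible target errors", {
  cam <- small_camera()
  # 2x2 grid with a pitch so large every node projects beyond the sensor
  huge <- target_spec(1000, n_rows = 2, n_cols = 2, patches = NULL)
  expect_error(project_target(scene_spec(cam, 100, target = huge,
                                         noise_sigma = 0)),
               "outside the field of view")
  # an oversized 7x9 grid keeps its central nodes and flags the rest
  big <- target_spec(40, patches = NULL)
  proj <- project_target(scene_spec(cam, 100, target = big, noise_sigma = 0))
  expect_gt(proj$n_dropped, 0)
  expect_equal(nrow(proj$nodes$ideal) + proj$n_dropped, 7 * 9)
})

test_that("colour attenuation follows Beer-Lambert and clips to range", {
  att <- attenuation_model(0.5, 0.1, 0.05)
  expect_equal(attenuate_color(c(120, 90, 60), att, 0), c(120, 90, 60))
  expect_equal(attenuate_color(c(120, 90, 60), attenuation_model(0, 0, 0), 7),
               c(120, 90, 60))
  expect_equal(attenuate_color(c(200, 0, 0), attenuation_model(0.5, 0, 0), 3)[1],
               44.62603202968596, tolerance = 1e-12)
  expect_true(all(attenuate_color(c(255, 255, 255), att, 100) >= 0))
})

test_that("scene invariants are enforced", {
  cam <- small_camera()
  expect_error(scene_spec(cam, -5), "distance_cm")
  expect_error(scene_spec(cam, 300, noise_sigma = 1, seed = NULL), "seed")
  expect_silent(scene_spec(cam, 300, noise_sigma = 0, seed = NULL))
})

test_that("rendering is deterministic for a given seed", {
  a <- render_scene(small_scene(noise_sigma = 2, seed = 5))
  b <- render_scene(small_scene(noise_sigma = 2, seed = 5))
  c <- render_scene(small_scene(noise_sigma = 2, seed = 6))
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c$image))
})

test_that("rendering does not disturb the global RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(render_scene(small_scene(noise_sigma = 2, seed = 5)))
  expect_identical(rnorm(1), before)
})

test_that("noiseless rendered grids are detected to sub-pixel accuracy", {
  scene <- small_scene(distance_cm = 200, d = 0, noise_sigma = 0)
  ren <- render_scene(scene)
  det <- detect_nodes(ren$image)
  expect_equal(nrow(det), nrow(ren$truth$nodes$observed))
  expect_lt(max(match_errors(det, ren$truth$nodes$observed)), 0.25)
})

test_that("rendered patch means match the attenuated colours", {
  scene <- small_scene(distance_cm = 300, d = 1e-4, noise_sigma = 2, seed = 9)
  ren <- render_scene(scene)
  meas <- extract_patch_rgb(ren$image, ren$truth$patches)
  diff <- abs(as.matrix(meas[, c("r", "g", "b")]) - ren$truth$patch_rgb_attenuated)
  # sampling error of a mean over >= 30x30 px at noise sd 2, plus clipping
  expect_lt(max(diff), 1)
  # and exactly equal without noise
  ren0 <- render_scene(small_scene(distance_cm = 300, d = 1e-4, noise_sigma = 0))
  meas0 <- extract_patch_rgb(ren0$image, ren0$truth$patches)
  expect_equal(as.matrix(meas0[, c("r", "g", "b")]),
               ren0$truth$patch_rgb_attenuated,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("fixtures round-trip through PNG and sidecar", {
  dir <- withr::local_tempdir()
  files <- make_fixtures(dir, camera = small_camera(), distances_m = c(2, 4),
                         noise_sigma = 1, seed = 3)
  expect_true(all(file.exists(files$image), file.exists(files$sidecar)))
  sc <- read_sidecar(files$sidecar[1])
  expect_equal(sc$params$distance_cm, 200)
  img <- read_image(files$image[1])
  expect_equal(dim(img), c(600, 800, 3))
  # PNG quantizes to 8 bits; detection still matches the sidecar truth
  det <- detect_nodes(img)
  expect_lt(max(match_errors(det, sc$nodes$observed)), 0.5)
})
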