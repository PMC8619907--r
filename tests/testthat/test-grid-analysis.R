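# Measurement extraction: node detection under noise, matching, span
# measurement, patch sampling, attenuation fitting.

test_that("node detection fails informatively on unusable images", {
  blank <- array(235, dim = c(200, 300, 3))
  expect_error(detect_nodes(blank), "detection failure")
  set.seed(1)
  scatter <- array(runif(200 * 300 * 3, 0, 255), dim = c(200, 300, 3))
  expect_error(detect_nodes(scatter), "detection failure")
})

test_that("node localization stays below half a pixel under noise sd 2", {
  errs <- vapply(1:6, function(s) {
    ren <- render_scene(small_scene(distance_cm = 250, d = 1e-4,
                                    noise_sigma = 2, seed = s))
    det <- detect_nodes(ren$image)
    mean(match_errors(det, ren$truth$nodes$observed))
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("matching pairs detected and ideal nodes one-to-one", {
  scene <- small_scene(distance_cm = 300, d = 0, noise_sigma = 0)
  proj <- project_target(scene)
  # identity: feeding the true observed positions matches every node
  m <- match_nodes(proj$nodes$observed, scene$target, scene$camera, 300)
  expect_equal(nrow(m$ideal), nrow(proj$nodes$ideal))
  expect_equal(unname(m$observed), unname(proj$nodes$observed))
  expect_identical(attr(m, "n_unmatched"), 0L)
  # correct pairing under strong distortion of either sign
  for (d0 in c(-1.5e-4, 1.5e-4)) {
    sc <- small_scene(distance_cm = 300, d = d0, noise_sigma = 0)
    pr <- project_target(sc)
    mm <- match_nodes(pr$nodes$observed, sc$target, sc$camera, 300)
    expect_equal(unname(mm$ideal), unname(pr$nodes$ideal))
  }
})

test_that("matching rejects random scatter", {
  scene <- small_scene(distance_cm = 300, d = 0, noise_sigma = 0)
  set.seed(4)
  scatter <- cbind(runif(40, -350, 350), runif(40, -250, 250))
  expect_error(match_nodes(scatter, scene$target, scene$camera, 300),
               "matching failure")
  expect_error(match_nodes(cbind(0, 0), scene$target, scene$camera, 300),
               "at least 3")
})

test_that("measured spans reproduce the configured FOV", {
  cam <- small_camera()
  for (D in c(150, 400)) {
    scene <- small_scene(distance_cm = D, d = 1.3e-4, noise_sigma = 1, seed = 2)
    ren <- render_scene(scene)
    cal <- calibrate_image(ren$image, scene$target, cam, D)
    expect_lt(abs(cal$fov_deg - fov_in_water(cam)), 0.5)
  }
})

test_that("span measurement scales as a pinhole and rejects degenerate grids", {
  scene1 <- small_scene(distance_cm = 200, d = 0, noise_sigma = 0)
  p1 <- project_target(scene1)
  scene2 <- scene_spec(small_camera(), 400, target = scene1$target,
                       distortion = distortion_model(0), noise_sigma = 0)
  p2 <- project_target(scene2)
  s1 <- measure_span(p1$nodes, scene1$target, 200)
  s2 <- measure_span(p2$nodes, scene1$target, 400)
  expect_equal(s1$dx_pix, 2 * s2$dx_pix, tolerance = 1e-9)
  # single column of nodes has zero physical span
  col <- cbind(rep(5, 4), c(-30, -10, 10, 30))
  expect_error(measure_span(node_set(col, col), scene1$target, 200),
               "single column")
})

test_that("patch extraction averages the central region and checks bounds", {
  img <- array(235, dim = c(100, 160, 3))
  img[31:70, 41:120, 1] <- 17
  img[31:70, 41:120, 2] <- 120
  img[31:70, 41:120, 3] <- 200
  layout <- data.frame(patch_id = "p", cx = 0, cy = 0, w = 80, h = 40)
  got <- extract_patch_rgb(img, layout)
  expect_equal(unlist(got[1, c("r", "g", "b")]), c(r = 17, g = 120, b = 200))
  off <- data.frame(patch_id = "edge", cx = 75, cy = 0, w = 40, h = 40)
  expect_error(extract_patch_rgb(img, off), "outside the image")
})

test_that("attenuation fit recovers generating coefficients exactly", {
  att <- attenuation_model(0.6, 0.15, 0.08)
  ref <- data.frame(patch_id = c("a", "b"), r = c(220, 140), g = c(80, 200),
                    b = c(60, 240))
  rows <- do.call(rbind, lapply(1:6, function(D) {
    vals <- attenuate_color(as.matrix(ref[, c("r", "g", "b")]), att, D)
    data.frame(distance_m = D, patch_id = rep(ref$patch_id, 3),
               channel = rep(c("r", "g", "b"), each = 2),
               value = c(vals[, 1], vals[, 2], vals[, 3]))
  }))
  fit <- fit_attenuation(rows, reference = ref)
  expect_equal(unname(coef(fit)), c(0.6, 0.15, 0.08), tolerance = 1e-6)
  expect_true(all(fit$r_squared > 1 - 1e-9))
  # zero attenuation data yields zero coefficients
  rows0 <- transform(rows, value = mapply(
    function(p, ch) ref[[ch]][match(p, ref$patch_id)], patch_id, channel))
  expect_equal(unname(coef(fit_attenuation(rows0, reference = ref))), c(0, 0, 0))
})

test_that("attenuation fit matches a brute-force 1-D search per channel", {
  att <- attenuation_model(0.43, 0.12, 0.06)
  ref <- data.frame(patch_id = "w", r = 240, g = 240, b = 240)
  set.seed(8)
  rows <- do.call(rbind, lapply(1:6, function(D) {
    vals <- pmax(attenuate_color(c(240, 240, 240), att, D) + rnorm(3, 0, 1), 1)
    data.frame(distance_m = D, patch_id = "w", channel = c("r", "g", "b"),
               value = vals)
  }))
  fit <- fit_attenuation(rows, reference = ref)
  for (ch in c("r", "g", "b")) {
    sub <- fit$data[fit$data$channel == ch, ]
    k_bf <- grid_search_k(sub$distance_m, -log(sub$value / sub$reference))
    expect_lte(abs(coef(fit)[ch] - k_bf), 1e-4)
  }
})

test_that("channels fully below the floor are flagged unfittable", {
  rows <- data.frame(distance_m = rep(1:3, each = 3),
                     patch_id = "p",
                     channel = rep(c("r", "g", "b"), 3),
                     value = rep(c(2, 100, 150), 3),
                     reference = rep(c(200, 200, 200), 3))
  fit <- fit_attenuation(rows)
  expect_identical(fit$unfittable, "r")
  expect_true(is.na(coef(fit)["r"]))
  expect_false(anyNA(coef(fit)[c("g", "b")]))
  expect_error(fit_attenuation(rows[rows$distance_m == 1, ]), "2 distinct")
})

test_that("seawater-like series show red attenuating fastest", {
  pe <- render_scene(small_scene(distance_cm = 100, noise_sigma = 1, seed = 21))
  qe <- render_scene(small_scene(distance_cm = 500, noise_sigma = 1, seed = 22))
  tab <- rbind(chart_measurements(pe$image, pe$truth$patches, 1),
               chart_measurements(qe$image, qe$truth$patches, 5))
  k <- coef(fit_attenuation(tab))
  expect_gt(k["r"], k["g"])
  expect_gt(k["r"], k["b"])
})
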