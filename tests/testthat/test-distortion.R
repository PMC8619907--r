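# Distortion model: forward transform, least-squares fit, inversion for
# points and images.

test_that("forward distortion matches hand-evaluated examples", {
  expect_equal(apply_distortion(cbind(300, 400), distortion_model(0)),
               cbind(x = 300, y = 400))
  # radial, d = 1e-4, r = 500: scale 1.05
  expect_equal(apply_distortion(cbind(300, 400), distortion_model(1e-4)),
               cbind(x = 315, y = 420), tolerance = 1e-12)
  # literal form adds the same scalar d*r to both coordinates
  expect_equal(apply_distortion(cbind(300, 400),
                                distortion_model(1e-4, "literal")),
               cbind(x = 300.05, y = 400.05), tolerance = 1e-12)
})

test_that("positive d moves nodes outward (pincushion), negative inward", {
  p <- regular_grid(1000)
  p <- p[rowSums(p^2) > 0, ]
  r0 <- sqrt(rowSums(p^2))
  r_pin <- sqrt(rowSums(apply_distortion(p, distortion_model(2e-4))^2))
  r_bar <- sqrt(rowSums(apply_distortion(p, distortion_model(-2e-4))^2))
  expect_true(all(r_pin > r0))
  expect_true(all(r_bar < r0))
  expect_identical(distortion_label(2e-4), "pincushion")
  expect_identical(distortion_label(-2e-4), "barrel")
})

test_that("fit recovers the generating coefficient exactly, both forms", {
  ideal <- regular_grid(1000)
  for (form in c("radial", "literal")) {
    for (d0 in c(-5e-4, -1.3e-4, 0, 1e-5, 1.3e-4, 5e-4)) {
      obs <- apply_distortion(ideal, distortion_model(d0, form))
      fit <- fit_distortion(node_set(ideal, obs), form = form)
      expect_equal(fit$d, d0, tolerance = 1e-9)
      expect_lt(fit$rms, 1e-9)
    }
  }
})

test_that("fit on identical node sets gives d = 0 with zero residual", {
  ideal <- regular_grid(800)
  fit <- fit_distortion(node_set(ideal, ideal))
  expect_identical(fit$d, 0)
  expect_identical(fit$rms, 0)
  expect_identical(fit$label, "none")
})

test_that("fit is unbiased under node noise (sd 0.5 px, 9x9 grid)", {
  ideal <- regular_grid(1000, 9)
  d0 <- 1.3e-4
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    obs <- apply_distortion(ideal, distortion_model(d0)) +
      matrix(rnorm(length(ideal), 0, 0.5), ncol = 2)
    fit_distortion(node_set(ideal, obs))$d - d0
  }, numeric(1))
  expect_lt(mean(abs(errs)), 2e-5)
})

test_that("closed-form fit agrees with a brute-force grid search", {
  ideal <- regular_grid(1000, 9)
  for (form in c("radial", "literal")) {
    set.seed(42)
    obs <- apply_distortion(ideal, distortion_model(1.1e-4, form)) +
      matrix(rnorm(length(ideal), 0, 0.4), ncol = 2)
    ns <- node_set(ideal, obs)
    d_hat <- fit_distortion(ns, form = form)$d
    d_bf <- grid_search_d(ns, form, d_hat - 2e-5, d_hat + 2e-5, step = 1e-7)
    expect_lte(abs(d_hat - d_bf), 1e-7)
  }
})

test_that("fitted sign follows the mean radial displacement", {
  ideal <- regular_grid(900, 7)
  for (d0 in c(-1.5e-4, 1.5e-4)) {
    set.seed(7)
    obs <- apply_distortion(ideal, distortion_model(d0)) +
      matrix(rnorm(length(ideal), 0, 0.3), ncol = 2)
    fit <- fit_distortion(node_set(ideal, obs))
    disp <- rowSums((obs - ideal) * ideal) / pmax(sqrt(rowSums(ideal^2)), 1e-9)
    expect_identical(fit$d > 0, mean(disp) > 0)
  }
})

test_that("degenerate fits are rejected", {
  expect_error(fit_distortion(node_set(cbind(0, 0), cbind(0, 0))), "at least 3")
  z <- matrix(0, 5, 2)
  expect_error(fit_distortion(node_set(z, z)), "degenerate")
})

test_that("undistort is the inverse of apply for points", {
  set.seed(99)
  p <- cbind(runif(200, -700, 700), runif(200, -500, 500))
  for (form in c("radial", "literal")) {
    for (d0 in c(-1.5e-4, 1.5e-4)) {
      m <- distortion_model(d0, form)
      expect_lt(max(abs(undistort_points(apply_distortion(p, m), m) - p)), 1e-6)
      expect_lt(max(abs(apply_distortion(undistort_points(p, m), m) - p)), 1e-6)
    }
  }
  m0 <- distortion_model(0)
  expect_equal(unname(undistort_points(p, m0)), unname(p))
})

test_that("distortion fit object supports the standard methods", {
  ideal <- regular_grid(600, 5)
  obs <- apply_distortion(ideal, distortion_model(2e-4))
  fit <- fit_distortion(node_set(ideal, obs))
  expect_named(coef(fit), "d")
  expect_equal(dim(residuals(fit)), dim(ideal))
  expect_equal(predict(fit, cbind(100, 0))[1, "x"],
               apply_distortion(cbind(100, 0), fit$model)[1, "x"])
  expect_output(print(fit), "pincushion")
  expect_output(summary(fit), "radial displacement")
})

test_that("node sets round-trip through CSV", {
  ideal <- regular_grid(400, 4)
  obs <- apply_distortion(ideal, distortion_model(1e-4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_node_set(node_set(ideal, obs), path)
  back <- read_node_set(path)
  expect_equal(unname(back$ideal), unname(ideal))
  expect_equal(unname(back$observed), unname(obs))
})

test_that("image undistortion straightens a rendered grid", {
  scene <- small_scene(distance_cm = 300, d = 1.3e-4, noise_sigma = 0)
  ren <- render_scene(scene)
  corr <- undistort_image(ren$image, scene$distortion, fill = 235)
  det <- detect_nodes(corr)
  errs <- match_errors(det, ren$truth$nodes$ideal)
  expect_lt(max(errs), 0.5)
})

test_that("undistorting with d = 0 is the identity; empty images error", {
  img <- array(runif(60 * 80 * 3, 0, 255), dim = c(60, 80, 3))
  expect_identical(undistort_image(img, distortion_model(0)), img)
  expect_error(undistort_image(array(0, c(0, 4, 3)), distortion_model(1e-4)),
               "empty image")
})

test_that("corrected pincushion frames have filled corners", {
  scene <- small_scene(distance_cm = 300, d = 2e-4, noise_sigma = 0)
  ren <- render_scene(scene)
  corr <- undistort_image(ren$image, scene$distortion, fill = -1)
  # corner pixels sample outside the original frame -> fill value
  expect_identical(corr[1, 1, 1], -1)
  expect_identical(corr[dim(corr)[1], dim(corr)[2], 3], -1)
  # center untouched by fill
  expect_gt(corr[300, 400, 1], 0)
})
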