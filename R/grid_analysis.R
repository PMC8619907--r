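# Measurement extraction from target images: node detection, matching,
# span measurement, colour-patch sampling and attenuation fitting.

# Box mean over a (2*ry+1) x (2*rx+1) window, edges truncated. Integral-image
# implementation, O(n) per axis.
box_mean <- function(m, ry, rx) {
  run_mean_rows <- function(m, r) {
    if (r <= 0) return(m)
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    i <- seq_len(n)
    i1 <- pmax(i - r, 1)
    i2 <- pmin(i + r, n)
    (cs[i2 + 1, , drop = FALSE] - cs[i1, , drop = FALSE]) / (i2 - i1 + 1)
  }
  t(run_mean_rows(t(run_mean_rows(m, ry)), rx))
}

shift_cols <- function(m, k) {
  # shift content by k columns (k > 0: content moves right), edge-replicated
  n <- ncol(m)
  idx <- pmin(pmax(seq_len(n) - k, 1), n)
  m[, idx, drop = FALSE]
}

luminance <- function(image) {
  if (length(dim(image)) == 3) {
    (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  } else {
    image
  }
}

#' Detect grid nodes at sub-pixel precision
#'
#' Finds the intersections of the dark grid lines in a calibration-target
#' image. A line-specific response is computed for each orientation (mean
#' darkness of a strip centred on the pixel minus the mean of two flanking
#' strips, which suppresses uniform regions and isolated edges); the
#' pointwise minimum of the vertical and horizontal responses peaks only
#' where two lines cross. Peaks are non-maximum suppressed and refined to
#' sub-pixel precision by centroiding the darkness profile along each axis
#' in a local window.
#'
#' @param image Image array (0-255) or grayscale matrix.
#' @param strip_halfwidth Half-width (px) of the line strip averaged across
#'   the line; should roughly cover the drawn line width. Default 4.
#' @param smooth_halflength Half-length (px) of averaging along the line.
#'   Default 6.
#' @param flank_offset Offset (px) of the flanking strips. Default 12.
#' @param min_sep Minimum separation between reported nodes, px. Default 20.
#' @param refine_halfwidth Half-size of the sub-pixel centroid window.
#'   Default 9.
#' @param threshold Absolute response threshold on the normalized (0-1)
#'   darkness scale. Default 0.15.
#' @return Matrix with columns `x`, `y`: node coordinates in center-relative
#'   pixels, sorted row-major (top to bottom, left to right).
#' @export
detect_nodes <- function(image, strip_halfwidth = 4, smooth_halflength = 6,
                         flank_offset = 12, min_sep = 20,
                         refine_halfwidth = 9, threshold = 0.15) {
  lum <- luminance(image)
  h <- nrow(lum); w <- ncol(lum)
  bg <- stats::quantile(lum, 0.80, names = FALSE)
  lo <- stats::quantile(lum, 0.02, names = FALSE)
  if (bg - lo < 10) {
    stop("node detection failure: image has no usable contrast (0 candidates)",
         call. = FALSE)
  }
  dk <- pmin(pmax((bg - lum) / (bg - lo), 0), 1.5)

  # flank subtraction uses the darker flank so half-plane features (colour
  # patches, their corners) cancel while thin lines survive
  bv <- box_mean(dk, smooth_halflength, strip_halfwidth)
  v_resp <- bv - pmax(shift_cols(bv, -flank_offset), shift_cols(bv, flank_offset))
  bh <- box_mean(dk, strip_halfwidth, smooth_halflength)
  h_resp <- bh - pmax(t(shift_cols(t(bh), -flank_offset)),
                      t(shift_cols(t(bh), flank_offset)))
  resp <- pmin(v_resp, h_resp)

  cand <- which(resp > threshold, arr.ind = TRUE)
  if (nrow(cand) < 9) {
    stop(sprintf("node detection failure: only %d candidate pixels above threshold",
                 nrow(cand)), call. = FALSE)
  }
  ord <- order(resp[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  acc <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) > min_sep^2) {
      acc <- rbind(acc, p)
    }
  }
  if (nrow(acc) < 9) {
    stop(sprintf("node detection failure: only %d distinct candidates found",
                 nrow(acc)), call. = FALSE)
  }

  # sub-pixel refinement: separable centroids of baseline-subtracted darkness
  refine <- function(row, col) {
    r0 <- max(1, row - refine_halfwidth); r1 <- min(h, row + refine_halfwidth)
    c0 <- max(1, col - refine_halfwidth); c1 <- min(w, col + refine_halfwidth)
    win <- dk[r0:r1, c0:c1, drop = FALSE]
    csum <- colSums(win); csum <- csum - min(csum)
    rsum <- rowSums(win); rsum <- rsum - min(rsum)
    if (sum(csum) <= 0 || sum(rsum) <= 0) return(c(col, row))
    c(sum(seq(c0, c1) * csum) / sum(csum),
      sum(seq(r0, r1) * rsum) / sum(rsum))
  }
  pts <- t(apply(acc, 1, function(p) refine(p[1], p[2])))
  # 1-based raster (col, row) -> center-relative (x, y)
  xy <- cbind(x = pts[, 1] - 1 - w / 2, y = pts[, 2] - 1 - h / 2)

  # row-major ordering: cluster by y, then sort by x within rows
  o <- order(xy[, 2])
  xy <- xy[o, , drop = FALSE]
  gap <- which(diff(xy[, 2]) > min_sep)
  row_id <- cumsum(c(1, seq_len(nrow(xy) - 1) %in% gap))
  xy[order(row_id, xy[, 1]), , drop = FALSE]
}

#' Match detected nodes to the projected ideal grid
#'
#' Projects the target's grid through the camera at the known distance,
#' aligns centroids, then pairs detected and ideal nodes by mutual nearest
#' neighbour. Unmatched nodes are dropped and counted; fewer than 50%
#' matched is an error.
#'
#' @param detected Matrix of detected node coordinates (center-relative px),
#'   e.g. from [detect_nodes()].
#' @param target A [target_spec()].
#' @param camera A [camera_model()].
#' @param distance_cm Camera-to-target distance, cm.
#' @param max_dist_frac Maximum pairing distance as a fraction of the node
#'   pitch in pixels. Default 0.45.
#' @return A [node_set()] (ideal, observed) restricted to matched pairs,
#'   with attribute `n_unmatched`.
#' @export
match_nodes <- function(detected, target, camera, distance_cm,
                        max_dist_frac = 0.45) {
  detected <- as_points(detected)
  if (nrow(detected) < 3) {
    stop("matching failure: need at least 3 detected nodes", call. = FALSE)
  }
  f <- focal_px(camera)
  pos <- grid_line_positions_cm(target)
  g <- expand.grid(y_cm = pos$y, x_cm = pos$x)
  ideal <- cbind(x = g$x_cm * f / distance_cm, y = g$y_cm * f / distance_cm)
  pitch_px <- target$node_pitch_cm * f / distance_cm
  max_d2 <- (max_dist_frac * pitch_px)^2

  shift <- colMeans(ideal) - colMeans(detected)
  det_al <- sweep(detected, 2, shift, `+`)
  d2 <- outer(det_al[, 1], ideal[, 1], `-`)^2 +
    outer(det_al[, 2], ideal[, 2], `-`)^2
  nn_di <- apply(d2, 1, which.min)
  nn_id <- apply(d2, 2, which.min)
  keep <- which(nn_id[nn_di] == seq_len(nrow(detected)) &
                  d2[cbind(seq_len(nrow(detected)), nn_di)] <= max_d2)
  # coverage is judged against the full ideal grid: random scatter pairs
  # some points by chance but never covers half the grid consistently
  n_possible <- nrow(ideal)
  if (length(keep) < 0.5 * n_possible) {
    stop(sprintf("matching failure: only %d of %d nodes matched",
                 length(keep), n_possible), call. = FALSE)
  }
  out <- node_set(ideal[nn_di[keep], , drop = FALSE],
                  detected[keep, , drop = FALSE])
  attr(out, "n_unmatched") <- n_possible - length(keep)
  out
}

#' Measure the reference-edge span from matched nodes
#'
#' Computes the pixel distance between the target's two reference edges (the
#' outermost grid-line columns), averaged over grid rows, and pairs it with
#' the known physical span and capture distance, ready for
#' [fov_from_span()]. Pass nodes whose observed coordinates have been
#' distortion-corrected (see [undistort_points()]) to measure the span free
#' of lens distortion.
#'
#' @param nodes A [node_set()] (ideal used for edge identification, observed
#'   for the measurement).
#' @param target A [target_spec()] providing `edge_span_cm`.
#' @param distance_cm Camera-to-target distance, cm.
#' @return A [span_measurement()].
#' @export
measure_span <- function(nodes, target, distance_cm) {
  stopifnot(inherits(nodes, "node_set"), inherits(target, "target_spec"))
  ix <- nodes$ideal[, 1]
  tol <- 1e-6 * max(1, max(abs(ix)))
  xl <- min(ix); xr <- max(ix)
  if (xr - xl <= tol) {
    stop("span error: nodes cover a single column (zero physical span)",
         call. = FALSE)
  }
  left <- abs(ix - xl) < tol
  right <- abs(ix - xr) < tol
  # pair edge nodes by grid row (ideal y)
  yl <- round(nodes$ideal[left, 2], 6)
  yr <- round(nodes$ideal[right, 2], 6)
  common <- intersect(yl, yr)
  if (!length(common)) {
    stop("span error: reference edges share no grid row", call. = FALSE)
  }
  dx <- vapply(common, function(y) {
    nodes$observed[right, 1][match(y, yr)] - nodes$observed[left, 1][match(y, yl)]
  }, numeric(1))
  span_measurement(target$edge_span_cm, mean(dx), distance_cm)
}

#' Mean RGB of colour-chart patches
#'
#' Averages each channel over the central 50% (by area) of each patch box —
#' a reproducible, noise-robust alternative to single-pixel colour picking.
#'
#' @param image Image array (`h x w x 3`, 0-255).
#' @param patches Patch layout with pixel-space columns `cx`, `cy`, `w`, `h`
#'   (center-relative pixels, as produced by [project_target()]) and
#'   `patch_id`.
#' @param shrink Linear shrink factor of the sampled region; default
#'   `sqrt(0.5)` (central 50% of the area).
#' @return Data frame `patch_id, r, g, b` of measured means.
#' @export
extract_patch_rgb <- function(image, patches, shrink = sqrt(0.5)) {
  dm <- dim(image)
  stopifnot(length(dm) == 3, dm[3] >= 3)
  h <- dm[1]; w <- dm[2]
  need <- c("patch_id", "cx", "cy", "w", "h")
  stopifnot(is.data.frame(patches), all(need %in% names(patches)))
  out <- patches["patch_id"]
  out$r <- NA_real_
  out$g <- NA_real_
  out$b <- NA_real_
  for (i in seq_len(nrow(patches))) {
    hw <- patches$w[i] * shrink / 2
    hh <- patches$h[i] * shrink / 2
    c0 <- floor(patches$cx[i] - hw + w / 2 + 1)
    c1 <- ceiling(patches$cx[i] + hw + w / 2 + 1)
    r0 <- floor(patches$cy[i] - hh + h / 2 + 1)
    r1 <- ceiling(patches$cy[i] + hh + h / 2 + 1)
    if (c0 < 1 || r0 < 1 || c1 > w || r1 > h) {
      stop(sprintf("patch '%s' (partially) outside the image",
                   patches$patch_id[i]), call. = FALSE)
    }
    if (c1 < c0 || r1 < r0) {
      stop(sprintf("patch '%s' has an empty sampling region",
                   patches$patch_id[i]), call. = FALSE)
    }
    for (ch in 1:3) {
      out[i, c("r", "g", "b")[ch]] <- mean(image[r0:r1, c0:c1, ch])
    }
  }
  out
}

#' Build a colour-measurement table from one chart image
#'
#' Joins measured patch means with the chart's reference values into the
#' long-format table consumed by [fit_attenuation()].
#'
#' @param image Image array (0-255).
#' @param patches Patch layout with pixel boxes and reference `r`, `g`, `b`
#'   (from [project_target()]).
#' @param distance_m Capture distance in meters.
#' @return Data frame `distance_m, patch_id, channel, value, reference`.
#' @export
chart_measurements <- function(image, patches, distance_m) {
  meas <- extract_patch_rgb(image, patches)
  do.call(rbind, lapply(c("r", "g", "b"), function(ch) {
    data.frame(
      distance_m = distance_m,
      patch_id = meas$patch_id,
      channel = ch,
      value = meas[[ch]],
      reference = patches[[ch]][match(meas$patch_id, patches$patch_id)]
    )
  }))
}

#' Fit per-channel attenuation coefficients
#'
#' Under Beer-Lambert attenuation a channel measured at distance `D` obeys
#' `value = reference * exp(-k D)`, i.e. `-log(value/reference) = k D`. Per
#' channel, `k` is the least-squares slope through the origin of the log
#' ratio against distance, pooled over patches. Observations with measured
#' value at or below `floor` (default 5 on the 0-255 scale) are excluded:
#' near-zero channels are dominated by noise and quantization after the log
#' transform. A channel with no usable observations is flagged unfittable.
#'
#' @param measurements Long-format table with columns `distance_m`,
#'   `patch_id`, `channel` (`"r"`, `"g"`, `"b"`), `value`, and `reference`
#'   (or supply `reference` separately).
#' @param reference Optional chart reference: data frame `patch_id, r, g, b`
#'   used to fill a missing `reference` column.
#' @param floor Exclusion floor on measured values, default 5.
#' @return An object of class `attenuation_fit`: coefficients `k` (m^-1,
#'   named r/g/b, `NA` where unfittable), per-channel `r_squared` and
#'   `n_obs`, `unfittable` channel names, and the filtered data.
#' @examples
#' ref <- c(200, 180, 160)
#' d <- rep(1:6, each = 3)
#' ch <- rep(c("r", "g", "b"), 6)
#' m <- data.frame(distance_m = d, patch_id = "p", channel = ch,
#'                 value = rep(ref, 6) * exp(-c(0.6, 0.15, 0.08) * d),
#'                 reference = rep(ref, 6))
#' coef(fit_attenuation(m))
#' @export
fit_attenuation <- function(measurements, reference = NULL, floor = 5) {
  stopifnot(is.data.frame(measurements),
            all(c("distance_m", "patch_id", "channel", "value") %in%
                  names(measurements)))
  if (!"reference" %in% names(measurements)) {
    stopifnot(is.data.frame(reference),
              all(c("patch_id", "r", "g", "b") %in% names(reference)))
    idx <- match(measurements$patch_id, reference$patch_id)
    measurements$reference <- mapply(function(i, ch) reference[[ch]][i],
                                     idx, measurements$channel)
  }
  if (length(unique(measurements$distance_m)) < 2) {
    stop("need measurements at >= 2 distinct distances", call. = FALSE)
  }
  channels <- c("r", "g", "b")
  k <- stats::setNames(rep(NA_real_, 3), channels)
  r2 <- stats::setNames(rep(NA_real_, 3), channels)
  n <- stats::setNames(integer(3), channels)
  kept <- list()
  for (ch in channels) {
    sub <- measurements[measurements$channel == ch &
                          measurements$value > floor &
                          measurements$reference > floor, , drop = FALSE]
    n[ch] <- nrow(sub)
    if (!nrow(sub)) next
    y <- -log(sub$value / sub$reference)
    D <- sub$distance_m
    k[ch] <- sum(D * y) / sum(D^2)
    ss_res <- sum((y - k[ch] * D)^2)
    ss_tot <- sum(y^2)
    r2[ch] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    kept[[ch]] <- sub
  }
  structure(
    list(
      k = k, r_squared = r2, n_obs = n,
      unfittable = channels[is.na(k)],
      floor = floor, data = do.call(rbind, kept)
    ),
    class = "attenuation_fit"
  )
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat("<attenuation_fit> k (m^-1):\n")
  for (ch in names(x$k)) {
    if (is.na(x$k[ch])) {
      cat(sprintf("  %s: unfittable (all observations below floor %.0f)\n",
                  ch, x$floor))
    } else {
      cat(sprintf("  %s: %.4f  (R^2 = %.4f, n = %d)\n",
                  ch, x$k[ch], x$r_squared[ch], x$n_obs[ch]))
    }
  }
  invisible(x)
}

#' @export
coef.attenuation_fit <- function(object, ...) object$k

#' @export
predict.attenuation_fit <- function(object, reference_rgb, distance_m, ...) {
  k <- ifelse(is.na(object$k), 0, object$k)
  attenuate_color(reference_rgb,
                  attenuation_model(k["r"], k["g"], k["b"]), distance_m)
}

#' @export
plot.attenuation_fit <- function(x, ...) {
  if (is.null(x$data)) stop("nothing to plot: no usable observations")
  cols <- c(r = "firebrick", g = "forestgreen", b = "royalblue")
  y <- -log(x$data$value / x$data$reference)
  graphics::plot(x$data$distance_m, y, col = cols[x$data$channel], pch = 16,
                 xlab = "distance (m)", ylab = "-log(value / reference)",
                 main = "per-channel attenuation", ...)
  for (ch in names(x$k)) {
    if (!is.na(x$k[ch])) graphics::abline(0, x$k[ch], col = cols[ch])
  }
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("k_%s = %.3f", names(x$k), x$k),
                   col = cols, lty = 1)
  invisible(x)
}

#' Convert a fitted attenuation to an attenuation model
#'
#' @param fit An `attenuation_fit`.
#' @return An [attenuation_model()] (unfittable channels become 0).
#' @export
as_attenuation_model <- function(fit) {
  stopifnot(inherits(fit, "attenuation_fit"))
  k <- ifelse(is.na(fit$k), 0, fit$k)
  attenuation_model(k["r"], k["g"], k["b"])
}
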