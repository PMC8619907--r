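#' One-coefficient grid-distortion model
#'
#' Radial image distortion parameterized by a single coefficient `d` (in
#' inverse pixels). Coordinates are center-relative pixels (origin at the
#' distortion center, x rightward, y downward). Two functional forms are
#' supported:
#'
#' * `form = "radial"` (default): `x' = x (1 + d r)`, `y' = y (1 + d r)` with
#'   `r = sqrt(x^2 + y^2)` — radially symmetric; `d > 0` moves every point
#'   away from the center (pincushion), `d < 0` toward it (barrel).
#' * `form = "literal"`: `x' = x + d r`, `y' = y + d r` — the same scalar
#'   offset `d r` added to both coordinates. Kept for fidelity to the
#'   grid-transform write-up this model derives from; it is not radially
#'   symmetric (a point on the y axis shifts horizontally).
#'
#' @param d Distortion coefficient, pix^-1.
#' @param form `"radial"` or `"literal"`.
#' @param center Optional distortion center `c(x, y)` in raster pixel
#'   coordinates (0-based, pixel centers at integers). `NULL` (default) means
#'   "the image center", resolved when an image operation is applied.
#' @return An object of class `distortion_model`.
#' @examples
#' m <- distortion_model(1.3e-4)
#' apply_distortion(cbind(300, 400), m)
#' @export
distortion_model <- function(d, form = c("radial", "literal"), center = NULL) {
  form <- match.arg(form)
  stopifnot(is.numeric(d), length(d) == 1, is.finite(d))
  if (!is.null(center)) {
    stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  }
  structure(list(d = d, form = form, center = center),
            class = "distortion_model")
}

#' @export
print.distortion_model <- function(x, ...) {
  cat(sprintf("<distortion_model> form = %s, d = %.6g pix^-1 (%s)\n",
              x$form, x$d, distortion_label(x$d)))
  invisible(x)
}

#' Classify the sign of a distortion coefficient
#'
#' @param d Distortion coefficient.
#' @return `"pincushion"` for `d > 0`, `"barrel"` for `d < 0`, `"none"` for 0.
#' @export
distortion_label <- function(d) {
  if (d > 0) "pincushion" else if (d < 0) "barrel" else "none"
}

as_points <- function(points) {
  p <- as.matrix(points)
  if (is.null(dim(p)) || ncol(p) != 2) {
    p <- matrix(as.numeric(points), ncol = 2)
  }
  storage.mode(p) <- "double"
  stopifnot(all(is.finite(p)))
  p
}

#' Apply grid distortion to points
#'
#' @param points Two-column matrix of center-relative pixel coordinates
#'   `(x, y)`.
#' @param model A [distortion_model()].
#' @return Matrix of distorted coordinates, same shape.
#' @export
apply_distortion <- function(points, model) {
  stopifnot(inherits(model, "distortion_model"))
  p <- as_points(points)
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  out <- switch(model$form,
    radial = p * (1 + model$d * r),
    literal = p + model$d * r
  )
  colnames(out) <- c("x", "y")
  out
}

#' Corresponding ideal/observed grid nodes
#'
#' Pairs the undistorted ("ideal") pixel coordinates of calibration-grid
#' nodes with their observed (distorted) image coordinates, index-aligned.
#' Coordinates are center-relative pixels.
#'
#' @param ideal,observed Two-column matrices `(x, y)`, equal row counts.
#' @return An object of class `node_set`.
#' @export
node_set <- function(ideal, observed) {
  ideal <- as_points(ideal)
  observed <- as_points(observed)
  if (nrow(ideal) != nrow(observed)) {
    stop("ideal and observed must have the same number of nodes", call. = FALSE)
  }
  structure(list(ideal = ideal, observed = observed), class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat(sprintf("<node_set> %d corresponding nodes, max |displacement| = %.3f px\n",
              nrow(x$ideal),
              if (nrow(x$ideal)) max(abs(x$observed - x$ideal)) else 0))
  invisible(x)
}

#' Read/write node sets as CSV
#'
#' Columns `x_ideal, y_ideal, x_obs, y_obs`, center-relative pixels.
#'
#' @param nodes A [node_set()].
#' @param path File path.
#' @return `read_node_set` returns a [node_set()]; `write_node_set` returns
#'   `path` invisibly.
#' @export
write_node_set <- function(nodes, path) {
  stopifnot(inherits(nodes, "node_set"))
  df <- data.frame(
    x_ideal = nodes$ideal[, 1], y_ideal = nodes$ideal[, 2],
    x_obs = nodes$observed[, 1], y_obs = nodes$observed[, 2]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_node_set
#' @export
read_node_set <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_ideal", "y_ideal", "x_obs", "y_obs")
  if (!all(need %in% names(df))) {
    stop("node-set CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  node_set(cbind(df$x_ideal, df$y_ideal), cbind(df$x_obs, df$y_obs))
}

#' Fit the distortion coefficient to corresponding nodes
#'
#' Least-squares estimate of the coefficient `d` from ideal vs observed node
#' coordinates. For both functional forms the model is linear in `d`, so the
#' fit is closed-form: stacking both coordinates of all nodes, the residual
#' `observed - ideal` equals `d` times a known regressor (`ideal * r` for the
#' radial form, `r` for the literal form), and `d` is the ordinary
#' least-squares slope through the origin.
#'
#' @param nodes A [node_set()] with at least 3 node pairs.
#' @param form `"radial"` (default) or `"literal"`; see [distortion_model()].
#' @return An object of class `distortion_fit` with components `d`, `form`,
#'   `rms` (root-mean-square residual in pixels, over both coordinates),
#'   `label` (barrel/pincushion/none), `n_nodes`, `model`
#'   (a [distortion_model()]), and the fitted/residual matrices.
#' @examples
#' ideal <- as.matrix(expand.grid(x = seq(-400, 400, 100),
#'                                y = seq(-400, 400, 100)))
#' obs <- apply_distortion(ideal, distortion_model(1.3e-4))
#' fit_distortion(node_set(ideal, obs))
#' @export
fit_distortion <- function(nodes, form = c("radial", "literal")) {
  stopifnot(inherits(nodes, "node_set"))
  form <- match.arg(form)
  if (nrow(nodes$ideal) < 3) {
    stop("need at least 3 corresponding node pairs to fit", call. = FALSE)
  }
  p <- nodes$ideal
  r <- sqrt(p[, 1]^2 + p[, 2]^2)
  if (all(r < .Machine$double.eps)) {
    stop("degenerate geometry: all nodes at the distortion center", call. = FALSE)
  }
  resp <- c(nodes$observed[, 1] - p[, 1], nodes$observed[, 2] - p[, 2])
  pred <- switch(form, radial = c(p[, 1] * r, p[, 2] * r), literal = c(r, r))
  if (sum(pred^2) < .Machine$double.eps) {
    stop("degenerate geometry: regressor identically zero", call. = FALSE)
  }
  d_hat <- sum(pred * resp) / sum(pred^2)
  model <- distortion_model(d_hat, form)
  fitted <- apply_distortion(p, model)
  resid <- nodes$observed - fitted
  structure(
    list(
      d = d_hat, form = form, rms = sqrt(mean(resid^2)),
      label = distortion_label(d_hat), n_nodes = nrow(p),
      model = model, nodes = nodes, fitted = fitted, residuals = resid
    ),
    class = "distortion_fit"
  )
}

#' @export
print.distortion_fit <- function(x, ...) {
  cat(sprintf(
    "<distortion_fit> form = %s: d = %.6g pix^-1 (%s), RMS residual %.4g px on %d nodes\n",
    x$form, x$d, x$label, x$rms, x$n_nodes
  ))
  invisible(x)
}

#' @export
coef.distortion_fit <- function(object, ...) c(d = object$d)

#' @export
residuals.distortion_fit <- function(object, ...) object$residuals

#' @export
fitted.distortion_fit <- function(object, ...) object$fitted

#' @export
predict.distortion_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$nodes$ideal else newdata
  apply_distortion(p, object$model)
}

#' @export
summary.distortion_fit <- function(object, ...) {
  print(object)
  disp <- object$nodes$observed - object$nodes$ideal
  cat(sprintf("  mean radial displacement: %+.3f px (%s)\n",
              mean(rowSums(disp * object$nodes$ideal) /
                     pmax(sqrt(rowSums(object$nodes$ideal^2)), 1e-12)),
              object$label))
  cat(sprintf("  max |residual|: %.4g px\n", max(abs(object$residuals))))
  invisible(object)
}

#' @export
plot.distortion_fit <- function(x, scale = 20, ...) {
  p <- x$nodes$ideal
  o <- x$nodes$observed
  graphics::plot(p, asp = 1, pch = 3, col = "grey40",
                 xlab = "x (px, center-relative)", ylab = "y (px)",
                 main = sprintf("distortion fit: d = %.3g (%s)", x$d, x$label),
                 ...)
  graphics::arrows(p[, 1], p[, 2],
                   p[, 1] + scale * (o[, 1] - p[, 1]),
                   p[, 2] + scale * (o[, 2] - p[, 2]),
                   length = 0.05, col = "firebrick")
  invisible(x)
}

#' Invert the distortion for points
#'
#' Finds the undistorted coordinates `p` such that
#' `apply_distortion(p, model)` reproduces the observed coordinates. For the
#' radial form the inverse is closed-form: the observed radius satisfies
#' `d r^2 + r - r_obs = 0`, solved for the physical (positive) root. For the
#' literal form a fixed-point iteration `p <- obs - d r(p)` is used. Well
#' posed while `|d| r < 0.5` over the image.
#'
#' @param points Two-column matrix of observed center-relative coordinates.
#' @param model A [distortion_model()].
#' @param tol Convergence tolerance in pixels (literal form), default 1e-9.
#' @param max_iter Iteration cap for the literal form, default 50.
#' @return Matrix of undistorted coordinates.
#' @export
undistort_points <- function(points, model, tol = 1e-9, max_iter = 50) {
  stopifnot(inherits(model, "distortion_model"))
  p <- as_points(points)
  d <- model$d
  if (d == 0) {
    colnames(p) <- c("x", "y")
    return(p)
  }
  if (model$form == "radial") {
    r_obs <- sqrt(p[, 1]^2 + p[, 2]^2)
    disc <- 1 + 4 * d * r_obs
    if (any(disc < 0)) {
      stop("inversion error: distortion too strong (no real root)", call. = FALSE)
    }
    # r_real / r_obs = 2 / (1 + sqrt(1 + 4 d r_obs)); finite at r_obs = 0
    out <- p * (2 / (1 + sqrt(disc)))
  } else {
    out <- p
    for (i in seq_len(max_iter)) {
      r <- sqrt(out[, 1]^2 + out[, 2]^2)
      nxt <- p - d * r
      delta <- max(abs(nxt - out))
      out <- nxt
      if (delta < tol) break
      if (i == max_iter) {
        stop("inversion error: fixed-point iteration did not converge",
             call. = FALSE)
      }
    }
  }
  colnames(out) <- c("x", "y")
  out
}

raster_center <- function(width, height, model = NULL) {
  if (!is.null(model) && !is.null(model$center)) model$center
  else c(width / 2, height / 2)
}

#' Undistort a raster image
#'
#' Resamples an image so straight scene lines become straight: the output
#' pixel at location `q` (center-relative) is sampled from the input at
#' `apply_distortion(q)` (inverse mapping) with bilinear interpolation.
#' Samples falling outside the input raster are set to `fill`. For a
#' pincushion coefficient the corrected frame has unfilled corners (the
#' corrected field of view is slightly non-square).
#'
#' @param image Numeric matrix (grayscale) or `h x w x c` array, values on
#'   any scale.
#' @param model A [distortion_model()]; its `center`, if set, is in 0-based
#'   raster coordinates, otherwise the image center is used.
#' @param fill Value for out-of-bounds samples (default 0).
#' @return Image of the same shape and class of values.
#' @export
undistort_image <- function(image, model, fill = 0) {
  stopifnot(inherits(model, "distortion_model"))
  dm <- dim(image)
  if (is.null(dm) || length(dm) < 2 || dm[1] == 0 || dm[2] == 0) {
    stop("empty image", call. = FALSE)
  }
  if (model$d == 0) return(image)
  h <- dm[1]; w <- dm[2]
  ctr <- raster_center(w, h, model)
  # center-relative coordinates of every output pixel (0-based raster grid)
  xs <- rep(0:(w - 1) - ctr[1], each = h)
  ys <- rep(0:(h - 1) - ctr[2], times = w)
  src <- apply_distortion(cbind(xs, ys), model)
  sample_bilinear(image, src[, 1] + ctr[1], src[, 2] + ctr[2], fill)
}

# Bilinear sampling of image (matrix or h x w x c) at 0-based raster
# coordinates (x = column, y = row); out-of-bounds -> fill.
sample_bilinear <- function(image, x, y, fill = 0) {
  dm <- dim(image)
  h <- dm[1]; w <- dm[2]
  nc <- if (length(dm) == 3) dm[3] else 1
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1 &
    (x0 + ifelse(fx > 0, 1, 0)) <= w - 1 & (y0 + ifelse(fy > 0, 1, 0)) <= h - 1
  x0c <- pmin(pmax(x0, 0), w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1)
  x1c <- pmin(x0c + 1, w - 1)
  y1c <- pmin(y0c + 1, h - 1)
  out <- array(fill, dim = c(h, w, nc))
  img <- if (nc == 1 && length(dm) == 2) array(image, dim = c(h, w, 1)) else image
  for (ch in seq_len(nc)) {
    plane <- img[, , ch]
    v <- (1 - fx) * (1 - fy) * plane[cbind(y0c + 1, x0c + 1)] +
      fx * (1 - fy) * plane[cbind(y0c + 1, x1c + 1)] +
      (1 - fx) * fy * plane[cbind(y1c + 1, x0c + 1)] +
      fx * fy * plane[cbind(y1c + 1, x1c + 1)]
    v[!ok] <- fill
    out[, , ch] <- v
  }
  if (nc == 1 && length(dm) == 2) out[, , 1] else out
}
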