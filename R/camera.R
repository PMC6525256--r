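#' Radial (Brown) camera distortion model
#'
#' Two-coefficient barrel/pincushion model: with normalized radius
#' r = |p - center| / scale, a world point at radius r images at
#' `r_d = r (1 + k1 r^2 + k2 r^4)`. Negative `k1` is barrel distortion, the
#' geometry typical of wide-angle endoscope optics.
#'
#' @param k1,k2 radial distortion coefficients (dimensionless)
#' @param center principal point `c(x, y)` in px (x = column, y = row,
#'   1-based pixel centers)
#' @param scale normalization radius in px
#' @return object of class `camera_model`
#' @export
camera_model <- function(k1 = 0, k2 = 0, center, scale) {
  if (scale <= 0) abort_param("camera scale must be positive")
  if (length(center) != 2L) abort_param("camera center must be c(x, y)")
  structure(list(k1 = k1, k2 = k2, center = as.numeric(center),
                 scale = as.numeric(scale)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: k1 = %.5g, k2 = %.5g, center = (%.1f, %.1f) px, scale = %.1f px\n",
              x$k1, x$k2, x$center[1L], x$center[2L], x$scale))
  rms <- attr(x, "rms_px")
  if (!is.null(rms)) cat(sprintf("  calibration RMS reprojection error: %.4f px\n", rms))
  invisible(x)
}

#' Apply / invert the radial distortion to point coordinates
#'
#' `distort_points` maps ideal (undistorted) points to where they appear on
#' the sensor; `undistort_points` inverts the radial map numerically
#' (Newton iteration). Round-tripping is accurate to well below 0.1 px for
#' `|k1| <= 0.5`, `|k2| <= 0.1` inside the field of view.
#'
#' @param camera a [camera_model()]
#' @param pts n x 2 matrix of `(x, y)` coordinates in px
#' @return n x 2 matrix of mapped coordinates
#' @export
distort_points <- function(camera, pts) {
  pts <- as_pts(pts)
  dx <- pts[, 1L] - camera$center[1L]
  dy <- pts[, 2L] - camera$center[2L]
  r <- sqrt(dx^2 + dy^2) / camera$scale
  g <- 1 + camera$k1 * r^2 + camera$k2 * r^4
  cbind(camera$center[1L] + dx * g, camera$center[2L] + dy * g)
}

#' @rdname distort_points
#' @export
undistort_points <- function(camera, pts) {
  pts <- as_pts(pts)
  dx <- pts[, 1L] - camera$center[1L]
  dy <- pts[, 2L] - camera$center[2L]
  rd <- sqrt(dx^2 + dy^2) / camera$scale
  r <- invert_radial(camera, rd)
  g <- ifelse(rd > 0, r / rd, 1)
  cbind(camera$center[1L] + dx * g, camera$center[2L] + dy * g)
}

# Solve r (1 + k1 r^2 + k2 r^4) = rd for r, vectorized Newton with a
# bisection-safe start at rd itself; the map is monotone for the supported
# coefficient range.
invert_radial <- function(camera, rd) {
  k1 <- camera$k1; k2 <- camera$k2
  r <- rd
  for (it in 1:25) {
    f <- r * (1 + k1 * r^2 + k2 * r^4) - rd
    fp <- 1 + 3 * k1 * r^2 + 5 * k2 * r^4
    fp[abs(fp) < 1e-12] <- 1e-12
    step <- f / fp
    r <- r - step
    if (max(abs(step)) < 1e-12) break
  }
  pmax(r, 0)
}

as_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  if (ncol(pts) != 2L) abort_param("points must be an n x 2 (x, y) matrix")
  pts
}

#' Calibrate the radial distortion model from point correspondences
#'
#' Least-squares fit of `(k1, k2)` from observed (distorted) image points and
#' their ideal grid positions, e.g. checkerboard corners: with normalized
#' radii `r` (ideal) and `r_d` (observed), `r_d - r` is regressed on
#' `(r^3, r^5)`. The RMS reprojection residual in px is attached to the
#' returned model.
#'
#' @param observed n x 2 matrix of distorted `(x, y)` points
#' @param reference n x 2 matrix of the corresponding ideal points
#' @param center principal point `c(x, y)` in px
#' @param scale normalization radius in px
#' @return a [camera_model()] with attribute `rms_px`
#' @export
calibrate_radial <- function(observed, reference, center, scale) {
  observed <- as_pts(observed); reference <- as_pts(reference)
  if (nrow(observed) != nrow(reference))
    abort_param("observed and reference point counts differ")
  ctr <- matrix(as.numeric(center), nrow(reference), 2L, byrow = TRUE)
  dref <- reference - ctr
  # degenerate geometry first: collinear points or a single common radius
  sv <- svd(scale(dref, scale = FALSE))$d
  r <- sqrt(rowSums(dref^2)) / scale
  if (sv[2L] < 1e-8 * max(sv[1L], 1) || stats::sd(r) < 1e-8 * max(mean(r), 1e-8))
    abort_data("ill-conditioned calibration geometry (collinear points or a single radius)")
  if (nrow(observed) < 12L)
    abort_param("calibration needs at least 12 point pairs (got %d)", nrow(observed))
  rd <- sqrt(rowSums((observed - ctr)^2)) / scale
  fit <- stats::lm.fit(cbind(r^3, r^5), rd - r)
  k <- fit$coefficients
  cam <- camera_model(k1 = k[1L], k2 = k[2L], center = center, scale = scale)
  proj <- distort_points(cam, reference)
  attr(cam, "rms_px") <- sqrt(mean(rowSums((proj - observed)^2)))
  cam
}

#' Resample a cube to remove radial lens distortion
#'
#' Each output pixel is bilinearly sampled from the recorded (distorted)
#' frame at its forward-distorted position, so straight world lines become
#' straight. Pixels whose source sample falls outside the original frame are
#' marked invalid in the returned cube's `valid_mask`; no valid pixels are
#' invented.
#'
#' @param cube a [spectral_cube()]
#' @param camera a [camera_model()]
#' @return the undistorted cube (same dimensions)
#' @export
undistort <- function(cube, camera) {
  d <- dim(cube$data)
  h <- d[1L]; w <- d[2L]
  grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w)) # (x, y)
  src <- distort_points(camera, grid)
  sx <- src[, 1L]; sy <- src[, 2L]
  inside <- sx >= 1 & sx <= w & sy >= 1 & sy <= h
  x0 <- pmin(pmax(floor(sx), 1L), w - 1L)
  y0 <- pmin(pmax(floor(sy), 1L), h - 1L)
  fx <- pmin(pmax(sx - x0, 0), 1)
  fy <- pmin(pmax(sy - y0, 0), 1)
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1L)
  i10 <- cbind(y0 + 1L, x0); i11 <- cbind(y0 + 1L, x0 + 1L)
  out <- array(0, d)
  for (k in seq_len(d[3L])) {
    b <- cube$data[, , k]
    v <- (1 - fy) * ((1 - fx) * b[i00] + fx * b[i01]) +
         fy * ((1 - fx) * b[i10] + fx * b[i11])
    v[!inside] <- 0
    out[, , k] <- matrix(v, h, w)
  }
  nn <- cbind(pmin(pmax(round(sy), 1L), h), pmin(pmax(round(sx), 1L), w))
  vm <- matrix(inside & cube$valid_mask[nn], h, w)
  res <- spectral_cube(out, cube$wavelengths_nm, vm, cube$meta)
  add_history(res, "undistort",
              list(k1 = camera$k1, k2 = camera$k2,
                   center = camera$center, scale = camera$scale))
}
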