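test_that("notch filter matches a direct FFT-bin-zeroing oracle and preserves DC", {
  h <- 64; w <- 40
  row <- matrix(seq_len(h) - 1, h, w)
  # constant image: unchanged
  const <- spectral_cube(array(7, c(h, w, 2)))
  out <- fourier_line_filter(const)
  expect_lt(max(abs(out$data - 7)), 1e-9)
  # on-notch oscillation is annihilated
  img <- 100 + 10 * sin(2 * pi * 0.25 * row)
  cube <- spectral_cube(array(img, c(h, w, 2)))
  filt <- fourier_line_filter(cube, 0.25)
  expect_lt(max(abs(filt$data[, , 1] - 100)), 1e-6 * 10)
  # off-notch frequency passes through unchanged (0.1 cycles/px is
  # bin-aligned on 80 rows, away from the notch bins 40/20/10)
  row80 <- matrix(seq_len(80) - 1, 80, w)
  img2 <- 100 + 10 * sin(2 * pi * 0.1 * row80)
  cube2 <- spectral_cube(array(img2, c(80, w, 2)))
  filt2 <- fourier_line_filter(cube2, c(0.5, 0.25, 0.125))
  expect_lt(max(abs(filt2$data[, , 1] - img2)) / max(abs(img2)), 1e-6)
  expect_error(fourier_line_filter(cube, 0.6), class = "ssv_param_error")
})

test_that("notch filter is idempotent", {
  ph <- small_phantom(h = 64, w = 48, seed = 5)
  once <- fourier_line_filter(ph$cube)
  twice <- fourier_line_filter(once)
  expect_lt(max(abs(twice$data - once$data)), 1e-9 * max(abs(once$data)))
})

test_that("radial distortion round-trips point coordinates within 0.1 px", {
  cam <- camera_model(k1 = -0.5, k2 = 0.1, center = c(100, 90), scale = 120)
  set.seed(6)
  pts <- cbind(runif(200, 10, 190), runif(200, 10, 170))
  back <- undistort_points(cam, distort_points(cam, pts))
  expect_lt(max(abs(back - pts)), 0.1)
})

test_that("calibration recovers known coefficients from synthetic checkerboards", {
  cam <- camera_model(k1 = -0.2, k2 = 0, center = c(200.5, 200.5), scale = 200)
  cb <- generate_checkerboard(cam)
  fit <- calibrate_radial(cb$distorted_corners, cb$ideal_corners,
                          center = cam$center, scale = cam$scale)
  expect_lt(abs(fit$k1 - (-0.2)), 0.01)
  expect_lt(attr(fit, "rms_px"), 0.1)
  # identity camera: coefficients vanish
  id <- camera_model(0, 0, c(140.5, 140.5), 140)
  cb0 <- generate_checkerboard(id)
  expect_identical(cb0$distorted_corners, cb0$ideal_corners)
  fit0 <- calibrate_radial(cb0$distorted_corners, cb0$ideal_corners,
                           center = id$center, scale = id$scale)
  expect_lt(max(abs(c(fit0$k1, fit0$k2))), 1e-6)
  # degenerate geometry
  coll <- cbind(seq(10, 30, 10), seq(10, 30, 10))
  expect_error(calibrate_radial(coll, coll, c(0, 0), 100),
               class = "ssv_data_error")
})

test_that("undistortion straightens checkerboard lines and never invents valid pixels", {
  cam <- camera_model(k1 = -0.2, k2 = 0, center = c(200.5, 200.5), scale = 200)
  cb <- generate_checkerboard(cam)
  # distorted corner rows bow away from straight lines
  line_residual <- function(pts) {
    max(vapply(split(seq_len(nrow(pts)), rep(1:7, each = 7)), function(i) {
      fit <- stats::lm.fit(cbind(1, pts[i, 1]), pts[i, 2])
      max(abs(fit$residuals))
    }, numeric(1)))
  }
  expect_gt(line_residual(cb$distorted_corners), 1)
  restored <- undistort_points(cam, cb$distorted_corners)
  expect_lt(line_residual(restored), 0.5)
  # identity resampling is exact; out-of-frame sources are masked
  ph <- small_phantom(h = 40, w = 40, seed = 7)
  idcam <- camera_model(0, 0, c(20, 20), 20)
  same <- undistort(ph$cube, idcam)
  expect_lt(max(abs(same$data - ph$cube$data)), 1e-9)
  expect_true(all(same$valid_mask))
  pin <- camera_model(k1 = 0.3, k2 = 0, c(20, 20), 20)  # pushes corners out
  outc <- undistort(ph$cube, pin)
  expect_false(outc$valid_mask[1, 1])
  expect_true(outc$valid_mask[20, 20])
  expect_identical(dim(outc$data), dim(ph$cube$data))
})

test_that("normalization standardizes per band and inverts exactly", {
  vals <- array(rep(c(0, 10), each = 8), c(4, 4, 2))
  cube <- spectral_cube(vals)
  nb <- normalize_bands(cube)
  expect_setequal(unique(as.vector(nb$cube$data)), c(-1, 1))
  back <- denormalize(nb$cube, nb$params)
  expect_lt(max(abs(back$data - vals)), 1e-9)

  ph <- small_phantom(h = 30, w = 30, seed = 8)
  nb2 <- normalize_bands(ph$cube)
  mus <- apply(nb2$cube$data, 3, mean)
  sds <- apply(nb2$cube$data, 3, function(b) sqrt(mean((b - mean(b))^2)))
  expect_lt(max(abs(mus)), 1e-9)
  expect_lt(max(abs(sds - 1)), 1e-9)
  expect_lt(max(abs(denormalize(nb2$cube, nb2$params)$data - ph$cube$data)),
            1e-9 * max(ph$cube$data))

  # affine arithmetic and error paths
  one <- spectral_cube(array(1, c(2, 2, 2)))
  p <- structure(list(loc = c(5, 5), scale = c(2, 2)),
                 class = "normalization_params")
  expect_equal(unique(as.vector(denormalize(one, p)$data)), 7)
  p3 <- structure(list(loc = rep(0, 3), scale = rep(1, 3)),
                  class = "normalization_params")
  expect_error(denormalize(one, p3), class = "ssv_param_error")
  flat <- spectral_cube(array(c(rep(3, 4), 1:4), c(2, 2, 2)))
  expect_error(normalize_bands(flat), "band 1", class = "ssv_data_error")
})

test_that("gaussian smoothing preserves the image sum, shrinks variance, matches the closed form", {
  const <- spectral_cube(array(3, c(16, 16, 2)))
  expect_lt(max(abs(gaussian_smooth(const, 1)$data - 3)), 1e-12)

  # impulse response = normalized sampled Gaussian
  imp <- array(0, c(21, 21, 2)); imp[11, 11, ] <- 1
  sm <- gaussian_smooth(spectral_cube(imp), 1)
  r <- ceiling(4)
  k1d <- exp(-((-r):r)^2 / 2); k1d <- k1d / sum(k1d)
  expect_lt(abs(sm$data[11, 11, 1] - k1d[r + 1]^2), 1e-6)
  expect_lt(abs(sm$data[11, 12, 1] - k1d[r + 1] * k1d[r + 2]), 1e-6)

  set.seed(9)
  noisy <- spectral_cube(array(rnorm(40 * 40 * 2), c(40, 40, 2)))
  out <- gaussian_smooth(noisy, 2)
  for (k in 1:2) {
    expect_lt(abs(sum(out$data[, , k]) - sum(noisy$data[, , k])) /
                abs(sum(noisy$data[, , k]) + 1), 1e-6)
    expect_lt(stats::var(as.vector(out$data[, , k])),
              stats::var(as.vector(noisy$data[, , k])))
  }
  expect_error(gaussian_smooth(noisy, 0), class = "ssv_param_error")
})

test_that("the pipeline applies the six steps in order and records them", {
  ph <- small_phantom(h = 48, w = 52, seed = 10)
  cfg <- pipeline_config(subimage_size = 12, mnf_cut = NULL)
  out <- run_pipeline(ph$cube, cfg)
  steps <- vapply(out$meta$history, `[[`, "", "step")
  expect_identical(steps, c("fourier_line_filter", "undistort",
                            "normalize_bands", "mnf_denoise", "denormalize",
                            "gaussian_smooth"))
  # with all MNF components kept, the pipeline equals notch + smoothing
  oracle <- gaussian_smooth(fourier_line_filter(ph$cube), 1)
  expect_lt(max(abs(out$data - oracle$data)) / max(abs(oracle$data)), 1e-6)
})

test_that("step order matters: smoothing before MNF denoising changes the result", {
  ph <- generate_phantom(variance_lesion_config(h = 60, w = 64, seed = 11))
  cfg <- pipeline_config(subimage_size = 12, mnf_cut = 3)
  pipe <- run_pipeline(ph$cube, cfg)
  # manual reordering: gaussian first, then the MNF chain
  x <- fourier_line_filter(ph$cube, cfg$notch_frequencies)
  x <- gaussian_smooth(x, cfg$gaussian_sigma)
  nb <- normalize_bands(x)
  res <- estimate_noise_residuum(nb$cube, cfg$subimage_size)
  tr <- fit_mnf(nb$cube, res)
  x <- denormalize(denoise(nb$cube, tr, 3), nb$params)
  expect_gt(max(abs(pipe$data - x$data)), 1e-3)
})
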