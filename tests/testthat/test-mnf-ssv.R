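test_that("residua vanish when the tile model nests the signal (affine data, OLS)", {
  h <- 40; w <- 44; L <- 3
  ri <- matrix(seq_len(h), h, w); ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  arr <- array(0, c(h, w, L))
  for (k in seq_len(L)) arr[, , k] <- 10 * k + 0.5 * k * ri + 0.2 * ci
  cube <- spectral_cube(arr)
  res <- estimate_noise_residuum(cube, 10)
  expect_lt(max(abs(res$residua[rep_mask(res)])), 1e-8)
  # border pixels are excluded, zero and masked
  expect_false(any(res$valid_mask[1, ]))
  expect_false(any(res$valid_mask[, 1]))
  expect_identical(unique(as.vector(res$residua[1, , ])), 0)
})

test_that("pooled residuum sd recovers injected iid noise within 10%", {
  set.seed(20)
  h <- 80; w <- 90; L <- 6
  ri <- matrix(seq_len(h), h, w); ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  arr <- array(0, c(h, w, L))
  for (k in seq_len(L))
    arr[, , k] <- 100 + 2 * k + 0.1 * ri + 0.05 * ci + rnorm(h * w, 0, 2)
  cube <- spectral_cube(arr)
  for (s in c(10, 25)) {
    res <- estimate_noise_residuum(cube, s)
    expect_lt(abs(stats::sd(res$residua[rep_mask(res)]) - 2) / 2, 0.1)
  }
})

test_that("residuum estimation validates tile size and flags undersized tiles", {
  cube <- tiny_cube(h = 20, w = 20, L = 3)
  expect_error(estimate_noise_residuum(cube, 30), class = "ssv_param_error")
  expect_error(estimate_noise_residuum(cube, 2), class = "ssv_param_error")
  # mask out almost an entire tile: it must be skipped with a warning
  vm <- matrix(TRUE, 20, 20); vm[1:10, 1:10] <- FALSE
  vm[2:4, 2] <- TRUE   # 3 usable pixels < 2 x predictor count
  cube2 <- spectral_cube(cube$data, valid_mask = vm)
  expect_warning(res <- estimate_noise_residuum(cube2, 10), "masked")
  expect_false(any(res$valid_mask[1:10, 1:10]))
})

test_that("the linear SVR regressor is available and behaves like a noise estimator", {
  set.seed(21)
  h <- 30; w <- 30
  arr <- array(100 + rnorm(h * w * 2, 0, 3), c(h, w, 2))
  cube <- spectral_cube(arr)
  res <- estimate_noise_residuum(cube, 15, regressor = "linear_svr")
  s <- stats::sd(res$residua[rep_mask(res)])
  expect_gt(s, 3 * 0.8); expect_lt(s, 3 * 1.2)
})

test_that("MNF whitens the noise and orders components by SNR", {
  # cube with known band-wise SNR: diagonal signal covariance + unit noise
  set.seed(22)
  h <- 90; w <- 100; L <- 6
  N <- h * w
  sig_sd <- sqrt(c(100, 25, 4, 1, 1, 1))
  smooth <- matrix(rnorm(N), h, w)
  smooth <- conv_sep_reflect_test(smooth)     # helper below: heavy smoothing
  smooth <- (smooth - mean(smooth)) / stats::sd(smooth)
  arr <- array(0, c(h, w, L))
  for (k in seq_len(L)) arr[, , k] <- sig_sd[k] * smooth + rnorm(N)
  cube <- spectral_cube(arr)
  res <- estimate_noise_residuum(cube, 15)
  tr <- fit_mnf(cube, res)
  # whitening: covariance of transformed residua ~ identity
  vm <- cube$valid_mask & res$valid_mask
  R2 <- matrix(res$residua, ncol = L)[which(vm), ]
  C <- stats::cov(R2 %*% tr$phi)
  offdiag <- sum(abs(C - diag(diag(C)))) / sum(abs(diag(C)))
  expect_lt(offdiag, 0.05)
  expect_lt(max(abs(diag(C) - 1)), 0.05)
  # SNR ordering is non-increasing and matches the eigen oracle's top space
  expect_true(all(diff(tr$s2[tr$snr_order]) <= 1e-9))
  expect_identical(tr$snr_order, seq_len(L))
  # leading MNF component recovers the common smooth signal direction
  B <- matrix(cube$data, ncol = L)[which(vm), ] %*% tr$phi
  expect_gt(abs(stats::cor(B[, 1], smooth[vm])), 0.99)
})

test_that("keeping all components is an identity round trip; truncation denoises a low-rank scene", {
  set.seed(23)
  ph <- generate_phantom(phantom_config(height = 64, width = 70,
                                        lesion = NULL, seed = 23))
  res <- estimate_noise_residuum(ph$cube, 16)
  tr <- fit_mnf(ph$cube, res)
  full <- denoise(ph$cube, tr, 6)
  expect_lt(max(abs(full$data - ph$cube$data)) / max(abs(ph$cube$data)), 1e-6)
  expect_equal(full$meta$history[[length(full$meta$history)]]$params$mnf_cut, 6L)
  # background is a rank-limited smooth scene: truncation must beat the input
  clean <- ph$cube$meta$background
  cut2 <- denoise(ph$cube, tr, 2)
  mse <- function(x) mean((x - clean)^2)
  expect_lt(mse(cut2$data), mse(ph$cube$data))
  # clamp and error paths
  clamp <- denoise(ph$cube, tr, 35)
  expect_lt(max(abs(clamp$data - ph$cube$data)) / max(abs(ph$cube$data)), 1e-6)
  expect_error(denoise(ph$cube, tr, 0), class = "ssv_param_error")
  expect_error(fit_mnf(ph$cube, structure(list(residua = array(0, dim(ph$cube$data)),
                                               valid_mask = ph$cube$valid_mask),
                                          class = "residuum_cube")),
               class = "ssv_data_error")
})

test_that("SSV maps follow the RMS and intensity-normalization arithmetic", {
  h <- 10; w <- 12; L <- 6
  cube <- spectral_cube(array(100, c(h, w, L)))
  resid <- array(0, c(h, w, L)); resid[, , 2] <- 5
  res <- structure(list(residua = resid, valid_mask = matrix(TRUE, h, w),
                        subimage_size = 10, regressor = "ols"),
                   class = "residuum_cube")
  maps <- ssv_maps(cube, res)
  expect_equal(unique(as.vector(maps$aggregate)), 5 / sqrt(6))
  expect_equal(unique(as.vector(maps$normalized)), 5 / sqrt(6) / 100)
  # zero residua -> all-zero maps
  res0 <- res; res0$residua[] <- 0
  maps0 <- ssv_maps(cube, res0)
  expect_true(all(maps0$aggregate == 0) && all(maps0$normalized == 0,
                                               na.rm = TRUE))
  # near-zero intensity pixels are masked in the normalized map
  dark <- cube; dark$data[1, 1, ] <- 0
  mapsd <- ssv_maps(dark, res)
  expect_true(is.na(mapsd$normalized[1, 1]))
  expect_false(anyNA(mapsd$normalized[-1, ]))
})

test_that("SSV separates a variance-only lesion from background", {
  ph <- generate_phantom(variance_lesion_config(h = 140, w = 150, seed = 24))
  filt <- fourier_line_filter(ph$cube)
  res <- estimate_noise_residuum(filt, 20)
  maps <- ssv_maps(filt, res)
  vm <- res$valid_mask
  inside <- maps$aggregate[vm & ph$mask$labels == 1L]
  outside <- maps$aggregate[vm & ph$mask$labels == 0L]
  expect_gt(mean(inside), mean(outside))
  p <- stats::wilcox.test(inside, outside, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("ssv_features emits bands + 1 uniquely named channels", {
  ph <- small_phantom(h = 30, w = 32, seed = 25)
  res <- estimate_noise_residuum(ph$cube, 10)
  fs <- ssv_features(res)
  expect_identical(channel_names(fs),
                   c(sprintf("ssv_b%d", 1:6), "ssv_rms"))
  expect_equal(dim(fs)[3], 7L)
  # zero residua give zero channels
  res$residua[] <- 0
  fs0 <- ssv_features(res)
  expect_true(all(fs0 == 0))
})
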