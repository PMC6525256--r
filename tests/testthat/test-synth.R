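test_that("phantoms are deterministic and decompose into composite + noise", {
  cfg <- variance_lesion_config(h = 100, w = 110, seed = 50)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$mask$labels, b$mask$labels)
  # noise-free configuration reproduces the composite exactly
  quiet <- generate_phantom(phantom_config(height = 50, width = 50,
                                           lesion = NULL, noise_sigma = 0,
                                           line_artifact = NULL, seed = 51))
  expect_identical(quiet$cube$data, quiet$cube$meta$background)
  # injected noise variance outside the lesion
  noise <- a$cube$data - a$cube$meta$background
  outside <- a$mask$labels == 0L
  v <- vapply(1:6, function(k) stats::var(noise[, , k][outside]), numeric(1))
  expect_true(all(abs(v - 25) / 25 < 0.1))
  # variance multiplier elevates lesion-local variance
  inside <- a$mask$labels == 1L
  vi <- stats::var(noise[, , 1][inside])
  expect_gt(vi, 2.5 * stats::var(noise[, , 1][outside]))
})

test_that("lesion area matches the ellipse and the config is validated", {
  cfg <- phantom_config(height = 200, width = 200,
                        lesion = list(center = c(100, 100), axes = c(40, 32),
                                      rotation_deg = 30, spectral_shift = 5,
                                      variance_multiplier = 2), seed = 52)
  ph <- generate_phantom(cfg)
  expect_lt(abs(sum(ph$mask$labels) - pi * 40 * 32) / (pi * 40 * 32), 0.01)
  expect_error(phantom_config(height = 100, width = 100,
                              lesion = list(center = c(50, 50),
                                            axes = c(60, 10),
                                            variance_multiplier = 2)),
               class = "ssv_param_error")
  expect_error(phantom_config(noise_sigma = -1), class = "ssv_param_error")
})

test_that("injected line artifacts are removed to < 1% of their energy by the notch filter", {
  cfg <- phantom_config(height = 128, width = 120, lesion = NULL,
                        noise_sigma = 0, seed = 53)
  ph <- generate_phantom(cfg)
  ref <- generate_phantom(phantom_config(height = 128, width = 120,
                                         lesion = NULL, noise_sigma = 0,
                                         line_artifact = NULL, seed = 53))
  filt <- fourier_line_filter(ph$cube)
  for (f in c(0.5, 0.25, 0.125)) {
    injected <- line_energy(ph$cube$data[, , 1], f) -
      line_energy(ref$cube$data[, , 1], f)
    remaining <- line_energy(filt$data[, , 1], f)
    expect_lt(remaining / injected, 0.01)
  }
})

test_that("checkerboards expose exact correspondences and distortion bends corner rows", {
  cam <- camera_model(k1 = -0.2, k2 = 0, center = c(200.5, 200.5),
                      scale = 200)
  cb <- generate_checkerboard(cam)
  expect_equal(nrow(cb$ideal_corners), 49L)
  expect_equal(dim(cb$image), c(cb$size, cb$size))
  # eight boards at varied poses give a richer calibration set
  poses <- lapply(1:8, function(i)
    generate_checkerboard(cam, squares = 6 + i %% 3,
                          square_px = 24 + 2 * i))
  obs <- do.call(rbind, lapply(poses, `[[`, "distorted_corners"))
  ideal <- do.call(rbind, lapply(poses, `[[`, "ideal_corners"))
  fit <- calibrate_radial(obs, ideal, center = cam$center, scale = cam$scale)
  expect_lt(abs(fit$k1 - (-0.2)), 0.01)
  expect_error(generate_checkerboard(cam, squares = 50, square_px = 100),
               class = "ssv_param_error")
})

test_that("cohorts are deterministic, patient-structured, and file round-trippable", {
  base <- phantom_config(height = 60, width = 64, lesion = list(
    center = c(30, 32), axes = c(12, 9), rotation_deg = 0,
    spectral_shift = 8, variance_multiplier = 2), seed = 1)
  coh1 <- generate_cohort(3, c(2, 2), base_config = base, seed = 60)
  coh2 <- generate_cohort(3, c(2, 2), base_config = base, seed = 60)
  expect_length(coh1, 6L)
  expect_identical(coh1[[4]]$cube$data, coh2[[4]]$cube$data)
  pats <- vapply(coh1, function(e) e$mask$patient_id, "")
  expect_length(unique(pats), 3L)
  expect_error(generate_cohort(1), class = "ssv_param_error")

  # zero inter-patient spread leaves patient backgrounds identical
  flat <- generate_cohort(2, c(1, 1), inter_patient_sigma = 0,
                          base_config = phantom_config(
                            height = 40, width = 40, lesion = NULL,
                            seed = 1),
                          seed = 61)
  expect_identical(flat[[1]]$cube$meta$background,
                   flat[[2]]$cube$meta$background)

  dirs <- withr::local_tempdir()
  mf <- generate_cohort(2, c(1, 2), base_config = base, dir = dirs,
                        seed = 62)
  expect_s3_class(mf, "dataset_manifest")
  expect_true(file.exists(file.path(dirs, "cohort_config.json")))
  loaded <- ssvmsi:::load_cohort(mf)
  expect_equal(dim(loaded[[1]]$cube$data)[3], 6L)
  expect_identical(dim(loaded[[1]]$mask$labels), c(60L, 64L))
})

test_that("stronger inter-patient variation lowers raw-band LOPO AUC", {
  base <- phantom_config(height = 80, width = 84, lesion = list(
    center = c(40, 42), axes = c(16, 12), rotation_deg = 10,
    spectral_shift = 12, variance_multiplier = 1), seed = 1)
  run_at <- function(sig) {
    coh <- generate_cohort(3, c(1, 1), inter_patient_sigma = sig,
                           base_config = base, seed = 63)
    stacks <- lapply(coh, function(e) raw_band_features(e$cube))
    ds <- dataset_from_stacks(stacks, lapply(coh, `[[`, "mask"))
    mean(train_eval_lopo(ds, "svm_linear", subsample_frac = 0.05,
                         min_per_class = 200, seed = 5)$auc)
  }
  expect_gt(run_at(0), run_at(25))
})
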