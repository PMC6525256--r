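#' Phantom configuration
#'
#' Describes a synthetic multispectral endoscopy phantom: a smooth per-band
#' background (low-order 2D polynomial surfaces on 8-bit-like intensities),
#' an elliptical lesion whose spectrum is shifted and/or whose local
#' variance is elevated, additive Gaussian sensor noise (sigma 5 intensity
#' values by default, the noise floor of the targeted endoscope system),
#' horizontal line artifacts at fixed spatial frequencies, and an optional
#' barrel-distorting camera. Defaults mirror the acquisition the pipeline
#' targets: 350 x 370 px, six bands on 400-650 nm.
#'
#' The lesion's mean spectral shift and its variance multiplier are
#' independently switchable, so gains specific to the SSV feature
#' (variance-only lesions) can be isolated from plain spectral gains.
#'
#' @param height,width spatial size in px
#' @param bands band count
#' @param wavelengths per-band center wavelengths in nm
#' @param lesion `NULL` for no lesion, or a list with `center` `(row, col)`,
#'   `axes` `(a, b)` in px, `rotation_deg`, `spectral_shift` (added to
#'   lesion pixels, recycled over bands) and `variance_multiplier`
#'   (multiplies the noise *variance* inside the lesion; >= 1)
#' @param noise_sigma additive Gaussian noise sd in intensity units
#' @param line_artifact named amplitudes of cosine line patterns, names =
#'   spatial frequencies in cycles/pixel
#' @param camera optional [camera_model()] applied to the captured frame
#' @param background_order 1 = affine background surfaces (exactly
#'   representable by the tile regressions), 2 = gently curved (default)
#' @param seed integer seed; identical config + seed gives bit-identical
#'   phantoms
#' @param background_seed optional separate seed for the background
#'   surfaces, so a cohort can share one anatomy while varying noise and
#'   lesions per image; defaults to `seed`
#' @return object of class `phantom_config`
#' @export
phantom_config <- function(height = 350, width = 370, bands = 6,
                           wavelengths = default_wavelengths(bands),
                           lesion = list(center = c(round(0.4 * height),
                                                    round(0.62 * width)),
                                         axes = c(round(height / 6),
                                                  round(height / 8)),
                                         rotation_deg = 20,
                                         spectral_shift = 10,
                                         variance_multiplier = 4),
                           noise_sigma = 5,
                           line_artifact = c("0.5" = 3, "0.25" = 3,
                                             "0.125" = 3),
                           camera = NULL, background_order = 2, seed = 1L,
                           background_seed = NULL) {
  if (noise_sigma < 0) abort_param("noise_sigma must be nonnegative")
  if (!is.null(lesion)) {
    if (any(lesion$axes <= 0)) abort_param("lesion axes must be positive")
    if ((lesion$variance_multiplier %||% 1) < 1)
      abort_param("lesion variance_multiplier must be >= 1")
    amax <- max(lesion$axes)
    if (lesion$center[1L] - amax < 1 || lesion$center[1L] + amax > height ||
        lesion$center[2L] - amax < 1 || lesion$center[2L] + amax > width)
      abort_param("lesion ellipse must lie fully inside the frame")
  }
  structure(list(height = height, width = width, bands = bands,
                 wavelengths = wavelengths, lesion = lesion,
                 noise_sigma = noise_sigma, line_artifact = line_artifact,
                 camera = camera, background_order = background_order,
                 seed = as.integer(seed),
                 background_seed = if (!is.null(background_seed))
                   as.integer(background_seed)),
            class = "phantom_config")
}

#' Generate a synthetic multispectral phantom
#'
#' Composition order mimics acquisition: scene (background + lesion
#' spectral shift) is warped by the optional camera distortion, then the
#' sensor adds line artifacts (cosine patterns parallel to the x-axis, so
#' the half-Nyquist 0.5 cycles/pixel component is representable) and
#' Gaussian noise, with elevated noise inside the lesion when a variance
#' multiplier is set. The noise-free background composite is kept in
#' `cube$meta$background` for verification.
#'
#' @param config a [phantom_config()]
#' @return `list(cube, mask)`: a [spectral_cube()] and a [label_mask()]
#'   (1 inside the lesion)
#' @export
generate_phantom <- function(config = phantom_config()) {
  set.seed(config$background_seed %||% config$seed)
  h <- config$height; w <- config$width; L <- config$bands
  u <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = h), h, w)
  # reflectance-like levels rising with wavelength, mid 8-bit range
  levels <- 90 + 90 * (config$wavelengths - min(config$wavelengths)) /
    max(diff(range(config$wavelengths)), 1)
  bg <- array(0, c(h, w, L))
  for (k in seq_len(L)) {
    co <- stats::runif(5, -1, 1)
    surf <- co[1L] * u + co[2L] * v
    if (config$background_order >= 2)
      surf <- surf + co[3L] * u * v + co[4L] * u^2 + co[5L] * v^2
    bg[, , k] <- levels[k] * (1 + 0.08 * surf)
  }
  set.seed(config$seed)   # noise/artifact stream, separate from anatomy

  inside <- matrix(FALSE, h, w)
  les <- config$lesion
  if (!is.null(les)) {
    th <- les$rotation_deg * pi / 180
    ri <- matrix(seq_len(h), h, w) - les$center[1L]
    ci <- matrix(seq_len(w), h, w, byrow = TRUE) - les$center[2L]
    a1 <- cos(th) * ri + sin(th) * ci
    a2 <- -sin(th) * ri + cos(th) * ci
    inside <- (a1 / les$axes[1L])^2 + (a2 / les$axes[2L])^2 <= 1
    shift <- rep_len(les$spectral_shift %||% 0, L)
    for (k in seq_len(L)) bg[, , k][inside] <- bg[, , k][inside] + shift[k]
  }

  scene <- bg
  if (!is.null(config$camera)) {
    # emulate the optics: captured(p) = scene(radially-inverted p)
    scene <- warp_capture(scene, config$camera)
    inside <- warp_capture_mask(inside, config$camera)
  }

  cube_data <- scene
  la <- config$line_artifact
  if (length(la)) {
    rowpat <- numeric(h)
    for (nm in names(la))
      rowpat <- rowpat + la[[nm]] *
        cos(2 * pi * as.numeric(nm) * (seq_len(h) - 1L))
    for (k in seq_len(L)) cube_data[, , k] <- cube_data[, , k] + rowpat
  }
  deterministic <- cube_data  # noise-free composite, kept for verification
  if (config$noise_sigma > 0) {
    sigma <- matrix(config$noise_sigma, h, w)
    if (!is.null(les))
      sigma[inside] <- config$noise_sigma *
        sqrt(les$variance_multiplier %||% 1)
    for (k in seq_len(L))
      cube_data[, , k] <- cube_data[, , k] + stats::rnorm(h * w) * sigma
  }

  cube <- spectral_cube(cube_data, config$wavelengths,
                        meta = list(background = deterministic,
                                    phantom_seed = config$seed))
  labels <- matrix(0L, h, w)
  labels[inside] <- 1L
  list(cube = cube, mask = label_mask(labels, patient_id = "synthetic",
                                      image_id = "phantom"))
}

warp_capture <- function(arr, camera) {
  d <- dim(arr)
  h <- d[1L]; w <- d[2L]
  grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
  src <- undistort_points(camera, grid)
  sx <- pmin(pmax(src[, 1L], 1), w)
  sy <- pmin(pmax(src[, 2L], 1), h)
  x0 <- pmin(floor(sx), w - 1L); y0 <- pmin(floor(sy), h - 1L)
  fx <- sx - x0; fy <- sy - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1L)
  i10 <- cbind(y0 + 1L, x0); i11 <- cbind(y0 + 1L, x0 + 1L)
  out <- array(0, d)
  for (k in seq_len(d[3L])) {
    b <- arr[, , k]
    out[, , k] <- matrix((1 - fy) * ((1 - fx) * b[i00] + fx * b[i01]) +
                           fy * ((1 - fx) * b[i10] + fx * b[i11]), h, w)
  }
  out
}

warp_capture_mask <- function(mask, camera) {
  h <- nrow(mask); w <- ncol(mask)
  grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
  src <- undistort_points(camera, grid)
  nn <- cbind(pmin(pmax(round(src[, 2L]), 1L), h),
              pmin(pmax(round(src[, 1L]), 1L), w))
  matrix(mask[nn], h, w)
}

#' Generate a synthetic calibration checkerboard
#'
#' Renders a checkerboard as captured through the given camera (radially
#' distorted) and returns exact corner correspondences for calibration
#' tests: the ideal interior-corner grid and its distorted image positions.
#'
#' @param camera a [camera_model()]
#' @param squares squares per side
#' @param square_px square edge length in px
#' @param frame_px frame edge length in px; the board is centered and must
#'   fit with a small margin
#' @return `list(image, distorted_corners, ideal_corners, size)`
#' @export
generate_checkerboard <- function(camera, squares = 8, square_px = 30,
                                  frame_px = 400) {
  board_px <- squares * square_px
  margin <- (frame_px - board_px) / 2
  if (margin < 4)
    abort_param("checkerboard (%d px) exceeds the %d px frame", board_px,
                frame_px)
  side <- frame_px
  ij <- seq_len(squares - 1L) * square_px + margin + 0.5
  ideal <- unname(as.matrix(expand.grid(x = ij, y = ij)))
  # board intensity: alternating squares, gray margin
  px <- seq_len(side) - margin - 0.5
  cellr <- matrix(floor(px / square_px), side, side)
  cellc <- t(cellr)
  board <- ifelse((cellr + cellc) %% 2 == 0, 0.85, 0.15)
  board[cellr < 0 | cellr >= squares | cellc < 0 | cellc >= squares] <- 0.5
  captured <- warp_capture(array(board, c(side, side, 1L)), camera)[, , 1L]
  list(image = captured,
       distorted_corners = distort_points(camera, ideal),
       ideal_corners = ideal, size = side)
}

#' Generate a synthetic multi-patient cohort
#'
#' Emulates the dominant difficulty of in-vivo multispectral endoscopy:
#' inter-patient variation. Each patient receives a random per-band offset
#' of the background spectra (sd `inter_patient_sigma`); each image jitters
#' the lesion's position, size and orientation. Cubes, masks, manifest and
#' the generating config are written to `dir` when given; otherwise the
#' cohort is returned in memory. Deterministic for a fixed seed.
#'
#' @param n_patients number of patients (>= 2)
#' @param images_per_patient inclusive range `c(lo, hi)` of images drawn
#'   per patient
#' @param inter_patient_sigma sd of the per-patient spectral offsets, in
#'   intensity units
#' @param base_config [phantom_config()] template shared by all images
#' @param dir output directory (created if missing), or `NULL` for an
#'   in-memory cohort
#' @param seed integer seed
#' @return in-memory: list of `list(cube, mask)` with a `manifest`
#'   attribute; on disk: the [read_manifest()] result for the written files
#' @export
generate_cohort <- function(n_patients = 4, images_per_patient = c(2, 3),
                            inter_patient_sigma = 8,
                            base_config = phantom_config(), dir = NULL,
                            seed = 1L) {
  if (n_patients < 2) abort_param("a cohort needs at least 2 patients")
  set.seed(seed)
  h <- base_config$height; w <- base_config$width
  entries <- list()
  manifest <- list()
  for (p in seq_len(n_patients)) {
    offs <- stats::rnorm(base_config$bands, 0, inter_patient_sigma)
    counts <- seq.int(images_per_patient[1L], images_per_patient[2L])
    n_img <- counts[sample.int(length(counts), 1L)]
    for (im in seq_len(n_img)) {
      cfg <- base_config
      cfg$seed <- as.integer((seed * 7919L + p * 101L + im) %% 2147483647L)
      cfg$background_seed <- base_config$background_seed %||%
        base_config$seed   # shared anatomy across the cohort
      if (!is.null(cfg$lesion)) {
        jit <- function(x, s, lo, hi) pmin(pmax(x + s, lo), hi)
        amax <- max(cfg$lesion$axes)
        set.seed(cfg$seed + 1L)
        cfg$lesion$center <- c(
          jit(cfg$lesion$center[1L], stats::rnorm(1, 0, h / 12),
              amax + 2, h - amax - 2),
          jit(cfg$lesion$center[2L], stats::rnorm(1, 0, w / 12),
              amax + 2, w - amax - 2))
        cfg$lesion$rotation_deg <- stats::runif(1, 0, 180)
        sc <- stats::runif(1, 0.8, 1.1)
        cfg$lesion$axes <- pmax(cfg$lesion$axes * sc, 15)
      }
      ph <- generate_phantom(cfg)
      for (k in seq_len(base_config$bands))
        ph$cube$data[, , k] <- ph$cube$data[, , k] + offs[k]
      ph$mask$patient_id <- sprintf("P%02d", p)
      ph$mask$image_id <- sprintf("P%02d_I%02d", p, im)
      entries[[length(entries) + 1L]] <- ph
      manifest[[length(manifest) + 1L]] <-
        data.frame(cube = sprintf("%s.tif", ph$mask$image_id),
                   mask = sprintf("%s_mask.png", ph$mask$image_id),
                   patient_id = ph$mask$patient_id,
                   image_id = ph$mask$image_id)
    }
  }
  manifest <- do.call(rbind, manifest)
  if (is.null(dir)) {
    attr(entries, "manifest") <- manifest
    return(entries)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(entries)) {
    write_cube(entries[[i]]$cube, file.path(dir, manifest$cube[i]))
    write_mask(entries[[i]]$mask, file.path(dir, manifest$mask[i]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  cfg_out <- base_config
  cfg_out$camera <- if (is.null(base_config$camera)) NULL else
    unclass(base_config$camera)
  jsonlite::write_json(
    list(n_patients = n_patients, images_per_patient = images_per_patient,
         inter_patient_sigma = inter_patient_sigma, seed = seed,
         base_config = unclass(cfg_out)),
    file.path(dir, "cohort_config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  read_manifest(file.path(dir, "manifest.csv"))
}
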