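#' Multispectral image cube
#'
#' The universal data container of the pipeline: a 3D intensity array indexed
#' `(row, col, band)` together with per-band center wavelengths and a
#' per-pixel validity mask (specular highlights, warped-out borders and other
#' unusable pixels are flagged invalid rather than removed, so masks and
#' feature maps stay co-registered with the cube).
#'
#' @param data numeric 3D array `(row, col, band)`, nonnegative units; at
#'   least 2 x 2 spatial pixels and 2 bands.
#' @param wavelengths_nm per-band center wavelengths in nm, strictly
#'   increasing. Defaults to `length(bands)` values evenly placed on
#'   \[400, 650\] nm, the six-band visible grid of the multispectral
#'   endoscope the pipeline targets.
#' @param valid_mask logical matrix with the cube's spatial dimensions;
#'   default all `TRUE`.
#' @param meta free-form provenance list; `meta$history` records one entry
#'   per processing operation applied to the cube.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelengths_nm = NULL, valid_mask = NULL,
                          meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_param("cube data must be a 3D array (row, col, band)")
  d <- dim(data)
  if (d[1L] < 2L || d[2L] < 2L)
    abort_param("cube must be at least 2 x 2 spatial pixels (got %d x %d)",
                d[1L], d[2L])
  if (d[3L] < 2L)
    abort_format("cube must have at least 2 bands (got %d)", d[3L])
  if (is.null(wavelengths_nm)) wavelengths_nm <- default_wavelengths(d[3L])
  if (length(wavelengths_nm) != d[3L])
    abort_param("wavelengths_nm has length %d but the cube has %d bands",
                length(wavelengths_nm), d[3L])
  if (any(diff(wavelengths_nm) <= 0))
    abort_param("wavelengths_nm must be strictly increasing")
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, d[1L], d[2L])
  if (!is.logical(valid_mask) || !identical(dim(valid_mask), d[1:2]))
    abort_param("valid_mask must be a logical matrix matching the cube's spatial dimensions")
  if (is.null(meta$history)) meta$history <- list()
  structure(
    list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
         valid_mask = valid_mask, meta = meta),
    class = "spectral_cube"
  )
}

default_wavelengths <- function(n_bands) seq(400, 650, length.out = n_bands)

#' @export
dim.spectral_cube <- function(x) dim(x$data)

n_bands <- function(cube) dim(cube$data)[3L]

#' Append a processing-history entry to a cube
#'
#' Every pipeline operation records itself here, so the order of applied
#' steps is externally observable.
#'
#' @param cube a `spectral_cube`
#' @param step character step name
#' @param params named list of the parameters the step used
#' @return the cube with one more `meta$history` entry
#' @export
add_history <- function(cube, step, params = list()) {
  cube$meta$history <- c(cube$meta$history,
                         list(list(step = step, params = params)))
  cube
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("spectral_cube: %d x %d px, %d bands (%s nm)\n",
              d[1L], d[2L], d[3L],
              paste(round(x$wavelengths_nm), collapse = ", ")))
  cat(sprintf("  intensity range: [%.4g, %.4g]; valid pixels: %d/%d\n",
              min(x$data), max(x$data), sum(x$valid_mask), prod(d[1:2])))
  if (length(x$meta$history)) {
    cat("  history:", paste(vapply(x$meta$history, `[[`, "", "step"),
                            collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
summary.spectral_cube <- function(object, ...) {
  vm <- object$valid_mask
  stats <- t(apply(object$data, 3L, function(b) {
    v <- b[vm]
    c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))
  }))
  rownames(stats) <- sprintf("b%d (%g nm)", seq_len(nrow(stats)),
                             object$wavelengths_nm)
  stats
}

#' Display one band of a cube as an image
#'
#' @param x a `spectral_cube`
#' @param band band index to show
#' @param ... passed to [graphics::image()]
#' @export
plot.spectral_cube <- function(x, band = 1L, ...) {
  m <- x$data[, , band]
  graphics::image(t(m)[, nrow(m):1], asp = nrow(m) / ncol(m),
                  col = grDevices::gray.colors(256), axes = FALSE,
                  main = sprintf("band %d (%g nm)", band,
                                 x$wavelengths_nm[band]), ...)
  invisible(x)
}

#' Per-pixel class labels aligned with a cube
#'
#' `0` codes healthy tissue, `1` carcinoma, `NA` unlabeled (ignore). The
#' ignore code is kept in place rather than dropping pixels, so label masks
#' stay co-registered with their cubes.
#'
#' @param labels integer matrix of 0 / 1 / NA
#' @param patient_id,image_id opaque identifiers
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, patient_id = "", image_id = "") {
  if (!is.matrix(labels)) abort_param("labels must be a matrix")
  lv <- labels[!is.na(labels)]
  if (length(lv) && !all(lv %in% c(0L, 1L)))
    abort_param("labels must be 0 (healthy), 1 (carcinoma) or NA (ignore)")
  structure(list(labels = labels, patient_id = as.character(patient_id),
                 image_id = as.character(image_id)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  n <- table(factor(x$labels, levels = c(0L, 1L)), useNA = "always")
  cat(sprintf(
    "label_mask %d x %d (patient %s, image %s): %d healthy, %d lesion, %d ignore\n",
    nrow(x$labels), ncol(x$labels), x$patient_id, x$image_id,
    n[["0"]], n[["1"]], sum(is.na(x$labels))))
  invisible(x)
}

check_mask_alignment <- function(cube, mask) {
  if (!identical(dim(mask$labels), dim(cube$data)[1:2]))
    abort_param("label mask (%d x %d) does not match cube (%d x %d)",
                nrow(mask$labels), ncol(mask$labels),
                dim(cube$data)[1L], dim(cube$data)[2L])
  invisible(TRUE)
}
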