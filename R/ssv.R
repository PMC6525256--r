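#' Spectral-spatial variation (SSV) maps
#'
#' The SSV is the residuum between the multispectral cube and its local
#' spatial-spectral regression fit: tissue whose local variance departs from
#' the sensor-noise floor — as carcinoma typically does — stands out. Three
#' maps are produced: the per-band residua, a 2D aggregate (per-pixel RMS
#' across bands), and the aggregate normalized by the pixel's mean intensity
#' (masked `NA` where the mean intensity is at or below `1e-6` of the image
#' maximum), which removes most of the illumination dependence.
#'
#' @param cube a [spectral_cube()]
#' @param residua the matching [estimate_noise_residuum()] result
#' @return object of class `ssv_maps` with fields `per_band`, `aggregate`,
#'   `normalized`
#' @export
ssv_maps <- function(cube, residua) {
  if (!identical(dim(residua$residua), dim(cube$data)))
    abort_param("residuum cube is not aligned with the data cube")
  agg <- sqrt(apply(residua$residua^2, c(1L, 2L), mean))
  meanI <- apply(cube$data, c(1L, 2L), mean)
  norm <- agg / meanI
  norm[meanI <= 1e-6 * max(cube$data)] <- NA_real_
  structure(list(per_band = residua$residua, aggregate = agg,
                 normalized = norm),
            class = "ssv_maps")
}

#' @export
print.ssv_maps <- function(x, ...) {
  cat(sprintf("ssv_maps: %d x %d x %d\n", dim(x$per_band)[1L],
              dim(x$per_band)[2L], dim(x$per_band)[3L]))
  cat(sprintf("  aggregate range [%.4g, %.4g]; normalized masked px: %d\n",
              min(x$aggregate), max(x$aggregate), sum(is.na(x$normalized))))
  invisible(x)
}

#' @export
plot.ssv_maps <- function(x, which = c("aggregate", "normalized"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  m[is.na(m)] <- 0
  graphics::image(t(m)[, nrow(m):1], asp = nrow(m) / ncol(m),
                  col = grDevices::hcl.colors(256, "viridis"), axes = FALSE,
                  main = sprintf("SSV (%s)", which), ...)
  invisible(x)
}

#' SSV feature channels
#'
#' Emits the per-band SSV channels plus the aggregate RMS channel
#' (`bands + 1` channels, named `ssv_b<k>` and `ssv_rms`) as a feature
#' stack fragment for classification.
#'
#' @param residua an [estimate_noise_residuum()] result
#' @return a [feature_stack()]
#' @export
ssv_features <- function(residua) {
  L <- dim(residua$residua)[3L]
  ch <- lapply(seq_len(L), function(k) residua$residua[, , k])
  names(ch) <- sprintf("ssv_b%d", seq_len(L))
  ch$ssv_rms <- sqrt(apply(residua$residua^2, c(1L, 2L), mean))
  feature_stack(ch)
}

#' Named per-pixel feature channels
#'
#' A stack of co-registered 2D feature planes (raw bands, SSV channels,
#' Laguerre-Gaussian responses) with unique, ordered channel names.
#'
#' @param channels named list of matrices with identical dimensions
#' @return object of class `feature_stack`: 3D array `(row, col, channel)`
#'   with channel names on the third dimension
#' @export
feature_stack <- function(channels) {
  if (!length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    abort_param("channels must be a non-empty named list")
  if (anyDuplicated(names(channels)))
    abort_param("channel names must be unique")
  dims <- vapply(channels, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    abort_param("all channels must share spatial dimensions")
  arr <- array(unlist(channels, use.names = FALSE),
               dim = c(dims[, 1L], length(channels)),
               dimnames = list(NULL, NULL, names(channels)))
  structure(arr, class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("feature_stack: %d x %d px, %d channels\n",
              dim(x)[1L], dim(x)[2L], dim(x)[3L]))
  cat("  ", paste(utils::head(channel_names(x), 12L), collapse = ", "),
      if (dim(x)[3L] > 12L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @rdname feature_stack
#' @param x a `feature_stack`
#' @export
channel_names <- function(x) dimnames(x)[[3L]]

#' Concatenate feature stacks
#'
#' @param ... `feature_stack` objects over the same pixel grid
#' @return a combined [feature_stack()]
#' @export
stack_bind <- function(...) {
  stacks <- list(...)
  ch <- do.call(c, lapply(stacks, function(s) {
    nm <- channel_names(s)
    stats::setNames(lapply(seq_along(nm), function(i) s[, , i]), nm)
  }))
  feature_stack(ch)
}

#' Raw per-band intensity channels of a cube as a feature stack
#'
#' @param cube a [spectral_cube()]
#' @return a [feature_stack()] with channels `band_b<k>`
#' @export
raw_band_features <- function(cube) {
  L <- n_bands(cube)
  ch <- lapply(seq_len(L), function(k) cube$data[, , k])
  names(ch) <- sprintf("band_b%d", seq_len(L))
  feature_stack(ch)
}
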