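#' Estimate the per-pixel noise residuum on disjoint sub-images
#'
#' The image is divided into disjoint square tiles (the last tile in each
#' direction absorbs the remainder, so tiles cover the image). Within each
#' tile, for every band, a linear model predicts each pixel's intensity from
#' its causal spatial neighbors in the same band (`I(i-1, j, k)` and
#' `I(i, j-1, k)`), the same pixel in the previous band (`I(i, j, k-1)`,
#' omitted for the first band), and the centered tile coordinates, with an
#' intercept — the spectral-spatial decorrelation (SSDC) scheme, augmented
#' with a local affine trend. The coordinate terms absorb smooth shading
#' noiselessly; without them, noisy neighbor predictors attenuate the fit on
#' large tiles and bias the noise estimate upward. The residuum
#' r = I - Ihat is taken as the noise; it feeds both the noise covariance
#' of the MNF transform and the SSV feature maps.
#'
#' Pixels on the image's first row/column lack spatial predictors and are
#' excluded from the fits; their residua are 0 and flagged invalid in the
#' returned mask, as are pixels in tiles too small to fit (fewer than twice
#' the predictor count of usable pixels, skipped with a warning).
#'
#' @param cube a [spectral_cube()]
#' @param subimage_size tile edge length in px (at least 4, no larger than
#'   the image; the methodological sweep range is 10-100)
#' @param regressor `"ols"` (deterministic default) or `"linear_svr"`
#'   (epsilon-insensitive linear support-vector regression,
#'   `epsilon = 0.1 * sd(band)` within the tile)
#' @return object of class `residuum_cube`: `residua` array aligned with the
#'   cube, `valid_mask`, `subimage_size`, `regressor`
#' @export
estimate_noise_residuum <- function(cube, subimage_size = 30,
                                    regressor = c("ols", "linear_svr")) {
  regressor <- match.arg(regressor)
  d <- dim(cube$data)
  h <- d[1L]; w <- d[2L]; L <- d[3L]
  if (subimage_size < 4) abort_param("subimage_size must be at least 4 px")
  if (subimage_size > min(h, w))
    abort_param("subimage_size (%d) exceeds the image (%d x %d)",
                subimage_size, h, w)

  up   <- cube$data[c(1L, seq_len(h - 1L)), , , drop = FALSE]
  left <- cube$data[, c(1L, seq_len(w - 1L)), , drop = FALSE]

  res <- array(0, d)
  rmask <- matrix(FALSE, h, w)
  rstart <- tile_starts(h, subimage_size)
  cstart <- tile_starts(w, subimage_size)
  skipped <- 0L

  for (ri in seq_along(rstart$from)) {
    rows <- rstart$from[ri]:rstart$to[ri]
    for (ci in seq_along(cstart$from)) {
      cols <- cstart$from[ci]:cstart$to[ci]
      sel <- expand.grid(i = rows[rows > 1L], j = cols[cols > 1L])
      if (!nrow(sel)) next
      ok <- cube$valid_mask[cbind(sel$i, sel$j)]
      sel <- sel[ok, , drop = FALSE]
      if (nrow(sel) < 2L * 6L) {  # < 2x max predictor count
        skipped <- skipped + 1L
        next
      }
      pix <- cbind(sel$i, sel$j)
      ic <- sel$i - mean(sel$i)
      jc <- sel$j - mean(sel$j)
      for (k in seq_len(L)) {
        idx <- cbind(pix, k)
        y <- cube$data[idx]
        X <- cbind(1, ic, jc, up[idx], left[idx],
                   if (k > 1L) cube$data[cbind(pix, k - 1L)])
        r <- switch(regressor,
          ols = {
            fit <- stats::lm.fit(X, y)
            fit$residuals
          },
          linear_svr = {
            s <- stats::sd(y)
            if (s < 1e-12) {
              y - mean(y)
            } else {
              sv <- e1071::svm(x = X[, -1L, drop = FALSE], y = y,
                               type = "eps-regression", kernel = "linear",
                               epsilon = 0.1 * s, scale = TRUE)
              y - stats::predict(sv, X[, -1L, drop = FALSE])
            }
          })
        res[idx] <- r
      }
      rmask[pix] <- TRUE
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d tile(s) had too few usable pixels; their residua are 0 and masked",
                    skipped), call. = FALSE)
  structure(list(residua = res, valid_mask = rmask,
                 subimage_size = subimage_size, regressor = regressor),
            class = "residuum_cube")
}

# disjoint tiles covering 1..n; the last tile absorbs the remainder
tile_starts <- function(n, size) {
  k <- max(1L, n %/% size)
  from <- seq.int(1L, by = size, length.out = k)
  to <- c(from[-1L] - 1L, n)
  list(from = from, to = to)
}

#' @export
print.residuum_cube <- function(x, ...) {
  cat(sprintf("residuum_cube: %d x %d x %d, subimage_size = %d, regressor = %s\n",
              dim(x$residua)[1L], dim(x$residua)[2L], dim(x$residua)[3L],
              x$subimage_size, x$regressor))
  cat(sprintf("  pooled residuum sd (valid px): %.4g\n",
              stats::sd(x$residua[rep_mask(x)])))
  invisible(x)
}

rep_mask <- function(x) {
  array(x$valid_mask, dim = dim(x$residua))
}

#' Fit the minimum noise fraction transform
#'
#' Builds the MNF factorization from the vectorized residuum matrix `R2`
#' (N x bands, valid pixels only) and data matrix `X2`:
#' the SVD of `R2` gives the eigen-expansion of the noise covariance
#' `R2' R2 / (N - 1)` (singular values squared); the data are whitened by
#' `W = X2 V1 S1^(-1/2)` (element-wise square root, pseudo-inverse with
#' tolerance `1e-10 * max`); a second SVD of `W` gives `V2`; the forward
#' transform is `Phi = V1 S1^(-1/2) V2` and its pseudo-inverse maps back.
#' Components of `B = X2 Phi` carry unit noise variance by construction, so
#' their data variances are their SNRs and arrive sorted in decreasing
#' order.
#'
#' @param cube a [spectral_cube()] (at least 2 bands)
#' @param residua the matching [estimate_noise_residuum()] result
#' @return object of class `mnf_transform` with fields `phi`, `phi_inv`,
#'   `s1` (noise-covariance eigenvalues), `s2` (whitened-data variances =
#'   component SNRs), `u1 = v1`, `v2`, `snr_order`, `n_pixels`
#' @export
fit_mnf <- function(cube, residua) {
  d <- dim(cube$data)
  L <- d[3L]
  if (L < 2L) abort_param("MNF needs at least 2 bands")
  if (!identical(dim(residua$residua), d))
    abort_param("residuum cube is not aligned with the data cube")
  vm <- cube$valid_mask & residua$valid_mask
  N <- sum(vm)
  if (N <= L) abort_data("too few valid pixels (%d) for an MNF fit", N)
  sel <- which(vm)
  R2 <- matrix(residua$residua, ncol = L)[sel, , drop = FALSE]
  X2 <- matrix(cube$data, ncol = L)[sel, , drop = FALSE]
  if (all(R2 == 0)) abort_data("residua are identically zero; MNF undefined")

  sv1 <- svd(R2 / sqrt(N - 1), nu = 0)
  d1 <- sv1$d
  tol <- 1e-10 * d1[1L]
  keep <- d1 > tol
  if (!all(keep))
    message(sprintf("fit_mnf: %d noise-covariance direction(s) below tolerance %.3g treated as zero",
                    sum(!keep), tol))
  inv_sqrt <- ifelse(keep, 1 / d1, 0)
  V1 <- sv1$v
  W <- X2 %*% V1 %*% diag(inv_sqrt, L)
  sv2 <- svd(W / sqrt(N - 1), nu = 0)
  V2 <- sv2$v
  s2 <- sv2$d^2
  phi <- V1 %*% diag(inv_sqrt, L) %*% V2
  phi_inv <- t(V2) %*% diag(ifelse(keep, d1, 0), L) %*% t(V1)
  structure(list(phi = phi, phi_inv = phi_inv,
                 s1 = d1^2, s2 = s2, u1 = V1, v1 = V1, v2 = V2,
                 snr_order = order(s2, decreasing = TRUE),
                 n_pixels = N, tol = tol),
            class = "mnf_transform")
}

#' @export
print.mnf_transform <- function(x, ...) {
  cat(sprintf("mnf_transform: %d bands, fitted on %d pixels\n",
              nrow(x$phi), x$n_pixels))
  cat("  component SNR (noise-whitened variance):",
      paste(sprintf("%.3g", x$s2), collapse = ", "), "\n")
  invisible(x)
}

#' MNF component-truncation denoising
#'
#' Projects the cube into MNF space (`B = X2 Phi`), zeroes all but the
#' `mnf_cut` leading (highest-SNR) components, and maps back through the
#' pseudo-inverse (`X = B* Phi^-1`). With `mnf_cut` equal to the band count
#' this is an identity round trip. Values above the band count clamp to all
#' components.
#'
#' @param cube a [spectral_cube()]
#' @param transform a fitted [fit_mnf()] transform
#' @param mnf_cut number of leading components retained (>= 1)
#' @return the denoised cube
#' @export
denoise <- function(cube, transform, mnf_cut) {
  L <- n_bands(cube)
  if (!is.numeric(mnf_cut) || mnf_cut < 1)
    abort_param("mnf_cut must be a positive component count")
  mnf_cut <- as.integer(min(mnf_cut, L))
  X2 <- matrix(cube$data, ncol = L)
  B <- X2 %*% transform$phi
  if (mnf_cut < L) B[, (mnf_cut + 1L):L] <- 0
  Xr <- B %*% transform$phi_inv
  res <- cube
  res$data <- array(Xr, dim(cube$data))
  add_history(res, "mnf_denoise", list(mnf_cut = mnf_cut))
}
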