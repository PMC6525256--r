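#' Generalized Laguerre polynomials, orders 0-3
#'
#' Closed forms of the Rodrigues definition
#' `L_p^l(x) = e^x x^(-l) / p! d^p/dx^p (e^(-x) x^(p+l))`:
#' `L_0^l = 1`, `L_1^l = -x + l + 1`,
#' `L_2^l = (x^2 - 2(l+2)x + (l+1)(l+2)) / 2`,
#' `L_3^l = (-x^3 + 3(l+3)x^2 - 3(l+2)(l+3)x + (l+1)(l+2)(l+3)) / 6`.
#' Orders above 3 are not supported: the filter bank is deliberately capped
#' to keep the feature count (and memory) small.
#'
#' @param p radial order, integer 0-3
#' @param l angular parameter, `l >= 0`
#' @param x evaluation points (vectorized)
#' @return `L_p^l(x)`, same length as `x`
#' @export
laguerre_poly <- function(p, l, x) {
  if (l < 0) abort_param("l must be nonnegative")
  switch(as.character(p),
    "0" = rep_len(1, length(x)),
    "1" = -x + l + 1,
    "2" = 0.5 * (x^2 - 2 * (l + 2) * x + (l + 1) * (l + 2)),
    "3" = (-x^3 + 3 * (l + 3) * x^2 - 3 * (l + 2) * (l + 3) * x +
             (l + 1) * (l + 2) * (l + 3)) / 6,
    abort_param("radial order p = %s unsupported (bank capped at p <= 3)",
                as.character(p))
  )
}

#' A single rotated Laguerre-Gaussian kernel
#'
#' Real Laguerre-Gaussian mode sampled on a `size x size` grid centered
#' mid-grid:
#' `k(r, phi) = (r sqrt(2)/w)^l L_p^l(2 r^2/w^2) exp(-r^2/w^2) cos(l (phi - rot))`,
#' normalized to unit L2 norm. The `cos(l phi)` angular factor makes every
#' `l >= 1` kernel zero-sum, so responses to constant images vanish; `l = 0`
#' is unsupported (its rotation step `180/l` is undefined and it would break
#' the zero-sum property).
#'
#' @param p radial order 0-3
#' @param l angular order 1-3
#' @param rotation_deg kernel rotation in degrees
#' @param size kernel edge length in px
#' @param gauss_width Gaussian envelope width `w` in px (default `size/4`)
#' @return `size x size` numeric matrix
#' @export
lg_kernel <- function(p, l, rotation_deg = 0, size = 40,
                      gauss_width = size / 4) {
  if (l < 1) abort_param("l = 0 kernels are unsupported (rotation step 180/l undefined)")
  if (size < 8) abort_param("kernel size must be at least 8 px")
  off <- seq_len(size) - (size + 1) / 2
  X <- matrix(off, size, size, byrow = TRUE)
  Y <- matrix(off, size, size)
  r2 <- X^2 + Y^2
  phi <- atan2(Y, X)
  w <- gauss_width
  k <- (sqrt(2 * r2) / w)^l * laguerre_poly(p, l, 2 * r2 / w^2) *
    exp(-r2 / w^2) * cos(l * (phi - rotation_deg * pi / 180))
  k / sqrt(sum(k^2))
}

#' Build a rotated Laguerre-Gaussian filter bank
#'
#' One kernel per `(p, l, rotation)`; for angular order `l`, the
#' `n_rotations` rotations are evenly spaced on `[0, 180/l)` degrees
#' (absolute responses make the remaining half-period redundant).
#'
#' @param p_set radial orders, subset of `0:3`
#' @param l_set angular orders, subset of `1:3`
#' @param n_rotations rotations per `(p, l)` pair
#' @param size kernel edge length in px
#' @param gauss_width Gaussian envelope width in px
#' @return object of class `lg_filter_bank`
#' @export
build_filter_bank <- function(p_set = 0:3, l_set = 1:3, n_rotations = 5,
                              size = 40, gauss_width = size / 4) {
  if (!length(p_set) || !length(l_set))
    abort_param("p_set and l_set must be non-empty")
  if (!all(p_set %in% 0:3)) abort_param("p_set must be a subset of 0:3")
  if (!all(l_set %in% 1:3))
    abort_param("l_set must be a subset of 1:3 (l = 0 unsupported)")
  if (n_rotations < 1) abort_param("n_rotations must be at least 1")
  kernels <- list()
  for (p in sort(p_set)) for (l in sort(l_set)) {
    step <- (180 / l) / n_rotations
    for (rot in (seq_len(n_rotations) - 1L) * step) {
      kernels[[length(kernels) + 1L]] <- list(
        kernel = lg_kernel(p, l, rot, size, gauss_width),
        p = p, l = l, rotation_deg = rot)
    }
  }
  structure(list(kernels = kernels, kernel_size = size,
                 gauss_width = gauss_width, n_rotations = n_rotations,
                 p_set = sort(p_set), l_set = sort(l_set)),
            class = "lg_filter_bank")
}

#' @export
print.lg_filter_bank <- function(x, ...) {
  cat(sprintf("lg_filter_bank: %d kernels (%d x %d px, w = %g px); p in {%s}, l in {%s}, %d rotations\n",
              length(x$kernels), x$kernel_size, x$kernel_size, x$gauss_width,
              paste(x$p_set, collapse = ","), paste(x$l_set, collapse = ","),
              x$n_rotations))
  invisible(x)
}

#' @export
plot.lg_filter_bank <- function(x, index = 1L, ...) {
  k <- x$kernels[[index]]
  graphics::image(k$kernel, col = grDevices::hcl.colors(256, "RdBu"),
                  axes = FALSE,
                  main = sprintf("LG kernel p=%d l=%d rot=%g", k$p, k$l,
                                 k$rotation_deg), ...)
  invisible(x)
}

#' Extract pooled Laguerre-Gaussian features from a cube
#'
#' For every band and every `(p, l)` pair, the cube is correlated with each
#' rotated kernel (reflective boundaries) and the per-pixel maximum of the
#' absolute responses over rotations is taken as the feature, so the same
#' lesion imaged from different directions yields comparable responses.
#' Channels are named `lg_p<p>_l<l>_b<k>`; the channel count is
#' `|p_set| x |l_set| x bands`, independent of the rotation count. The
#' default bank on a six-band cube yields 72 channels.
#'
#' @param cube a [spectral_cube()] with spatial size at least the kernel size
#' @param bank an [build_filter_bank()] bank
#' @return a [feature_stack()] with attribute `border_px` (half the kernel
#'   size; responses closer to the border mix in reflected content)
#' @export
extract_lg_features <- function(cube, bank) {
  d <- dim(cube$data)
  s <- bank$kernel_size
  if (d[1L] < s || d[2L] < s)
    abort_param("cube (%d x %d) is smaller than the kernel (%d px)",
                d[1L], d[2L], s)
  p <- s %/% 2L
  h <- d[1L]; w <- d[2L]
  H2 <- h + 2L * p; W2 <- w + 2L * p
  ridx <- c(pmin(p:1, h), 1:h, pmax(h - seq_len(p) + 1L, 1L))
  cidx <- c(pmin(p:1, w), 1:w, pmax(w - seq_len(p) + 1L, 1L))

  # kernel FFTs are shared across bands
  kf <- lapply(bank$kernels, function(kr) {
    K <- matrix(0, H2, W2)
    K[seq_len(s), seq_len(s)] <- kr$kernel
    Conj(stats::fft(K))
  })

  groups <- unique(lapply(bank$kernels, function(kr) c(kr$p, kr$l)))
  ch <- list()
  for (k in seq_len(d[3L])) {
    Ipad <- cube$data[, , k][ridx, cidx]
    Fi <- stats::fft(Ipad)
    resp <- lapply(kf, function(K)
      Re(stats::fft(Fi * K, inverse = TRUE))[seq_len(h) + 0L, seq_len(w) + 0L] /
        (H2 * W2))
    for (g in groups) {
      sel <- which(vapply(bank$kernels,
                          function(kr) kr$p == g[1L] && kr$l == g[2L],
                          logical(1L)))
      pooled <- abs(resp[[sel[1L]]])
      for (i in sel[-1L]) pooled <- pmax(pooled, abs(resp[[i]]))
      ch[[sprintf("lg_p%d_l%d_b%d", g[1L], g[2L], k)]] <- pooled
    }
  }
  out <- feature_stack(ch)
  attr(out, "border_px") <- p
  out
}
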