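# Shared fixture builders; everything is generated in code at test time.

tiny_cube <- function(h = 12, w = 14, L = 6, seed = 1) {
  set.seed(seed)
  spectral_cube(array(runif(h * w * L, 0, 255), c(h, w, L)))
}

# lesion-free phantom at reduced size, otherwise default conditions
small_phantom <- function(h = 120, w = 130, seed = 1, ...) {
  generate_phantom(phantom_config(height = h, width = w, lesion = NULL,
                                  seed = seed, ...))
}

# variance-only lesion phantom: the lesion differs from background solely
# by its noise variance, the configuration that isolates the SSV signal
variance_lesion_config <- function(h = 350, w = 370, multiplier = 4,
                                   seed = 1, ...) {
  phantom_config(height = h, width = w,
                 lesion = list(center = c(round(h * 0.4), round(w * 0.6)),
                               axes = c(round(h / 6), round(h / 8)),
                               rotation_deg = 20, spectral_shift = 0,
                               variance_multiplier = multiplier),
                 seed = seed, ...)
}

# independent FFT oracle: total spectral energy on the notch rows at +-f
line_energy <- function(m, f) {
  h <- nrow(m)
  u <- round(f * h)
  F <- Mod(stats::fft(m))^2
  sum(F[unique(c(u + 1, h - u + 1)), ])
}

# Rodrigues-form oracle for the generalized Laguerre polynomials: build
# d^p/dx^p (e^-x x^(p+l)) symbolically with stats::D, then evaluate.
laguerre_rodrigues <- function(p, l, x) {
  expr <- quote(exp(-x) * x^(p + l))
  expr <- do.call(substitute, list(expr, list(p = p, l = l)))
  for (i in seq_len(p)) expr <- stats::D(expr, "x")
  env <- new.env()
  env$x <- x
  exp(x) * x^(-l) / factorial(p) * eval(expr, env)
}

# heavy separable box-ish smoothing used to manufacture a smooth field
conv_sep_reflect_test <- function(m) {
  for (i in 1:4) {
    k <- rep(1 / 9, 9)
    n <- nrow(m)
    idx <- c(pmin(4:1, n), 1:n, pmax(n - 1:4 + 1, 1))
    mp <- m[idx, , drop = FALSE]
    acc <- matrix(0, n, ncol(m))
    for (t in 1:9) acc <- acc + k[t] * mp[(t - 1) + 1:n, , drop = FALSE]
    m <- t(acc); m <- m  # transpose to smooth the other axis next pass
  }
  m
}
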