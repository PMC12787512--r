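# Small deterministic fixtures shared across tests.

# cube with known, distinct band patterns
toy_cube <- function(h = 16L, w = 16L, b = 4L, seed = 99L) {
  set.seed(seed)
  vals <- array(runif(h * w * b), c(h, w, b))
  hyper_cube(vals, wavelength_grid(n_bands = b))
}

# two-band pair used for the frozen SSIM reference value
ssim_fixture <- function() {
  set.seed(424)
  a <- matrix(runif(24 * 24), 24, 24)
  b <- pmin(pmax(a * 0.7 + 0.3 * matrix(runif(24 * 24), 24, 24), 0), 1)
  list(a = a, b = b)
}

# deterministic 16x16 image for the wavelet reference values
dwt_fixture <- function() {
  outer(1:16, 1:16, function(i, j) sin(i / 2) * cos(j / 3) + 0.05 * i * j / 16)
}

# dense random texture whose score map yields far more than K candidates
dense_texture <- function(n = 96L, seed = 5L) {
  set.seed(seed)
  img <- matrix(runif(n * n), n, n)
  img <- 0.5 + 0.4 * sin(outer(1:n, 1:n, `+`) / 3) * img
  pmin(pmax(img, 0), 1)
}
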