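test_that("PCA first component recovers a rank-1 texture exactly", {
  set.seed(41)
  T0 <- matrix(runif(16 * 16, 0.1, 0.9), 16, 16)
  a <- runif(8, 0.2, 1)                      # positive band loadings
  vals <- array(as.vector(T0) %o% a, c(16, 16, 8))
  cube <- hyper_cube(vals, wavelength_grid(n_bands = 8))
  img <- pca_first_component(cube)
  expect_equal(unclass(img), xylospec:::norm01(T0), tolerance = 1e-10)
  expect_equal(range(img), c(0, 1))
  # scale invariance after normalization
  cube2 <- hyper_cube(vals * 0.37, wavelength_grid(n_bands = 8))
  expect_equal(unclass(pca_first_component(cube2)), unclass(img), tolerance = 1e-10)
})

test_that("randomized and exact PCA solvers agree", {
  set.seed(43)
  T0 <- matrix(runif(32 * 32), 32, 32)
  a <- runif(16, 0.3, 1)
  vals <- array(as.vector(T0) %o% a, c(32, 32, 16)) +
    array(rnorm(32 * 32 * 16, 0, 0.01), c(32, 32, 16))
  cube <- hyper_cube(pmin(pmax(vals, 0), 1), wavelength_grid(n_bands = 16))
  e <- pca_first_component(cube, "exact")
  r <- pca_first_component(cube, "randomized", seed = 2)
  expect_equal(unclass(e), unclass(r), tolerance = 1e-6)
})

test_that("Sobel features respond along the expected axes", {
  n <- 16
  ramp <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)  # varies along x
  f <- sobel_features(ramp)
  # interior Gx constant positive, Gy zero
  gx <- f[, , 1]; gy <- f[, , 2]
  expect_true(all(gy[2:(n - 1), 2:(n - 1)] == 0))
  expect_true(stats::sd(gx[2:(n - 1), 2:(n - 1)]) < 1e-12)
  expect_equal(sobel_features(matrix(1, 8, 8)), array(0, c(8, 8, 2)))
  # transpose equivariance swaps the channels
  set.seed(5)
  img <- matrix(runif(n * n), n, n)
  f1 <- sobel_features(img)
  f2 <- sobel_features(t(img))
  expect_equal(f2[, , 1], t(f1[, , 2]), tolerance = 1e-12)
  expect_equal(f2[, , 2], t(f1[, , 1]), tolerance = 1e-12)
})

test_that("moment kernels reproduce the analytic unit-image response", {
  I <- matrix(1, 15, 15)
  raw <- moment_features(I, w = 7, normalize = FALSE)
  # sum over the 7x7 window of x^2 = 7 * (9+4+1+0+1+4+9) = 196
  expect_equal(raw[8, 8, 1], 196)
  expect_equal(raw[8, 8, 2], 196)
  expect_equal(raw[8, 8, 3], 0)
  # normalized constant image: all channels zero (degenerate min = max)
  nm <- moment_features(I, w = 7)
  expect_equal(nm, array(0, c(15, 15, 3)))
  # I = x * y on centred coordinates has positive raw M11 at the centre
  xs <- matrix(rep(-7:7, each = 15), 15, 15)
  xy <- xs * t(xs)
  raw2 <- moment_features(xy / max(abs(xy)), w = 7, normalize = FALSE)
  expect_gt(raw2[8, 8, 3], 0)
})

test_that("Gabor bank is orientation selective with 6 channels", {
  k <- xylospec:::gabor_kernel(0)
  r <- (nrow(k) + 1) %/% 2
  expect_equal(k[r, r], 1)    # exp(0) * cos(0) at the origin
  n <- 48
  vstripe <- 0.5 + 0.5 * sin(2 * pi * matrix(rep(0:(n - 1), each = n), n, n) / 8)
  f <- gabor_features(vstripe)
  expect_equal(dim(f)[3], 6L)
  raw <- gabor_features(vstripe, normalize = FALSE)
  means <- apply(raw, 3, mean)
  expect_equal(which.max(means), 1L)   # theta = 0 wins on vertical stripes
  expect_true(all(f >= 0 & f <= 1))
})

test_that("modality scores follow the per-modality rules", {
  expect_warning(p <- modality_points(array(0, c(16, 16, 2)), "sobel"),
                 "constant")
  expect_equal(nrow(p), 0L)
  # gabor: max rule equals the dominating channel
  g <- array(0, c(16, 16, 6))
  set.seed(6)
  g[, , 3] <- matrix(runif(256, 0.5, 1), 16, 16)
  for (ch in c(1, 2, 4, 5, 6)) g[, , ch] <- g[, , 3] * 0.3
  s3 <- apply(g, c(1, 2), max)
  expect_equal(s3, g[, , 3])
  # dense texture saturates K per modality
  img <- dense_texture(96)
  sob <- sobel_features(img)
  pts <- modality_points(sob, "sobel", K = 100)
  expect_equal(nrow(pts), 100L)
})

test_that("the texture stack has 12 aligned, normalized channels", {
  sp <- make_species(2, seed = 55)[[1]]
  cube <- render_cube(sp, 32, 32, 16, seed = 55)
  fused <- fuse_bands(band_images(cube, c(1, 3, 5, 7, 9, 11, 13, 15, 2, 4)))
  pca <- pca_first_component(cube)
  sob <- sobel_features(pca); mom <- moment_features(pca); gab <- gabor_features(pca)
  stack <- build_texture_stack(fused, sob, mom, gab)
  expect_equal(dim(stack), c(32L, 32L, 12L))
  expect_identical(stack[, , 2:3], sob)     # concatenation is positional
  expect_true(all(stack >= 0 & stack <= 1))
  expect_error(build_texture_stack(fused, sob, mom, gab[1:16, , , drop = FALSE]),
               "shape")
  # all-constant inputs give an all-zero stack
  z <- build_texture_stack(matrix(0.5, 8, 8), array(0, c(8, 8, 2)),
                           array(0, c(8, 8, 3)), array(0, c(8, 8, 6)))
  expect_equal(unclass(z), array(0, c(8, 8, 12)), ignore_attr = TRUE)
})
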