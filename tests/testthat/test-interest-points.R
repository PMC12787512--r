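test_that("notch degrid removes an injected grid but not clean content", {
  sp <- make_species(2, seed = 13)[[1]]
  cube <- render_cube(sp, 96, 96, 8, seed = 13)
  img <- cube$values[, , 4]
  # clean image: operator is (near) identity
  out_clean <- notch_degrid(img)
  expect_lt(max(abs(out_clean - img)), 1e-3)
  # contaminated image: the grid's Fourier peak drops by >= 80%
  dirty <- add_grid_artifact(img, 8, 0.1)
  fidx <- 96 / 8   # grid frequency in FFT bins
  peak_mag <- function(m) {
    F <- Mod(stats::fft(m))
    max(F[1 + c(fidx, 96 - fidx), 1 + c(fidx, 96 - fidx)])
  }
  before <- peak_mag(dirty)
  cleaned <- notch_degrid(dirty)
  expect_gt(nrow(attr(cleaned, "peaks")), 0)
  expect_lt(peak_mag(cleaned), 0.2 * before)
})

test_that("the notch mask suppresses a peak centre by exactly alpha", {
  # one synthetic spike: mask value at the centre must be 1 - 0.85
  img <- matrix(0.5, 64, 64)
  img <- add_grid_artifact(img, 8, 0.2)
  out <- notch_degrid(img)
  peaks <- attr(out, "peaks")
  expect_gt(nrow(peaks), 0)
  F_in <- stats::fft(img)
  F_out <- stats::fft(out)
  i <- peaks[1, 1] %% 64; j <- peaks[1, 2] %% 64
  ratio <- Mod(F_out[i + 1, j + 1]) / Mod(F_in[i + 1, j + 1])
  # centre attenuation: (1 - alpha) possibly deepened by neighbouring notches
  expect_lt(ratio, 0.15 + 1e-6)
  expect_gt(ratio, 0.15 * 0.15 - 1e-6)
})

test_that("enhancement fixes constants and raises contrast of flat ramps", {
  flat <- matrix(0.4, 48, 48)
  expect_equal(enhance(flat), flat)
  ramp <- matrix(rep(seq(0.45, 0.55, length.out = 48), each = 48), 48, 48)
  out <- enhance(ramp)
  expect_gte(stats::sd(out), stats::sd(ramp))
  expect_true(all(out >= 0 & out <= 1))
  # gamma keeps the endpoints of [0,1]
  expect_equal(1^0.95, 1)
  hom <- enhance(ramp, homomorphic = TRUE)
  expect_true(all(hom >= 0 & hom <= 1))
})

test_that("score map is a convex combination of normalized features", {
  expect_equal(0.25 + 5 * 0.15, 1)
  set.seed(21)
  img <- matrix(runif(48 * 48), 48, 48)
  s <- score_map(img)
  expect_true(all(s >= 0 & s <= 1 + 1e-12))
  expect_error(score_map(img, weights = c(harris = 0.5, entropy = 0.1,
                                          sobel = 0.1, laplace = 0.1,
                                          dog = 0.1, snr = 0.05)), "sum to 1")
  # a single bright corner on a flat background dominates the score map
  corner <- matrix(0.2, 48, 48)
  corner[23:25, 23:25] <- 1
  sc <- unclass(score_map(corner))
  peak <- which(sc == max(sc), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - 24) <= 3))
})

test_that("point extraction honours threshold, spacing and ranking", {
  # one isolated peak
  s <- matrix(0, 32, 32); s[16, 16] <- 1
  pts <- extract_points(s)
  expect_equal(nrow(pts), 1L)
  expect_equal(c(pts$x, pts$y), c(15L, 15L))
  # two peaks 5 px apart (< d = 6): only the higher survives
  s2 <- matrix(0, 32, 32); s2[10, 10] <- 0.9; s2[10, 15] <- 0.8
  pts2 <- extract_points(s2, d = 6)
  expect_equal(nrow(pts2), 1L)
  expect_equal(pts2$score, 0.9)
  # with spacing 5 both survive, in descending order
  pts3 <- extract_points(s2, d = 5)
  expect_equal(pts3$score, c(0.9, 0.8))
  # empty map warns
  expect_warning(p0 <- extract_points(matrix(0, 8, 8)), "all-zero")
  expect_equal(nrow(p0), 0L)
})

test_that("dense textures yield exactly K spaced, descending points", {
  img <- dense_texture(96)
  s <- score_map(img)
  cand <- extract_points(s, t = 0.02, d = 6, K = 1e6)
  expect_gt(nrow(cand), 100)           # enough candidates to saturate K
  pts <- extract_points(s, t = 0.02, d = 6, K = 100)
  expect_equal(nrow(pts), 100L)
  expect_true(all(diff(pts$score) <= 0))
  dmat <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  expect_gte(min(dmat[upper.tri(dmat)]), 6)
  expect_true(all(pts$score >= 0 & pts$score <= 1))
})

test_that("spectra are sampled at point locations in ranking order", {
  sp <- make_species(2, seed = 31)[[1]]
  sp$noise_sd <- 0
  cube <- render_cube(sp, 32, 32, 16, seed = 3)
  pts <- structure(data.frame(x = c(5L, 0L, 31L), y = c(7L, 0L, 31L),
                              score = c(0.9, 0.5, 0.2)),
                   class = c("interest_points", "data.frame"))
  sig <- sample_spectra(cube, pts)
  expect_equal(dim(sig), c(3L, 16L))
  expect_equal(sig[1, ], as.vector(cube$values[8, 6, ]))
  expect_equal(sig[3, ], as.vector(cube$values[32, 32, ]))
  bad <- pts; bad$x[1] <- 32L
  expect_error(sample_spectra(cube, bad), "bounds")
  # full detection chain respects the K cap
  det <- detect_interest_points(dense_texture(32), K = 20, d = 3)
  expect_lte(nrow(det), 20)
})
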