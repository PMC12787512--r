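test_that("similarity matrices are symmetric with unit diagonal", {
  cube <- toy_cube(16, 16, 4)
  for (f in list(fddm_matrix, dhash_matrix, mi_matrix, ssim_matrix)) {
    S <- f(cube)
    expect_true(all(abs(S - t(S)) < 1e-12))
    expect_equal(as.vector(diag(S)), rep(1, 4))
    expect_true(all(S >= 0 & S <= 1))
    # diagonal entry is the row maximum
    expect_true(all(diag(S) >= apply(S, 1, max) - 1e-12))
  }
})

test_that("duplicated bands score similarity 1 under every metric", {
  set.seed(2)
  b1 <- matrix(runif(16 * 16), 16, 16)
  cube <- hyper_cube(array(c(b1, b1, runif(256), runif(256)), c(16, 16, 4)),
                     wavelength_grid(n_bands = 4))
  expect_equal(fddm_matrix(cube)[1, 2], 1)
  expect_equal(dhash_matrix(cube)[1, 2], 1)
  expect_equal(mi_matrix(cube)[1, 2], 1)
  expect_equal(ssim_matrix(cube)[1, 2], 1, tolerance = 1e-12)
})

test_that("difference hash flips every bit between a ramp and its negative", {
  ramp <- matrix(rep(seq(0, 1, length.out = 16), each = 16), 16, 16)
  cube <- hyper_cube(array(c(ramp, 1 - ramp, ramp, ramp), c(16, 16, 4)),
                     wavelength_grid(n_bands = 4))
  S <- dhash_matrix(cube)
  expect_equal(S[1, 2], 0)
  # quantization to multiples of 1/64
  expect_true(all(abs(S * 64 - round(S * 64)) < 1e-12))
})

test_that("mutual information is low for independent noise, invariant to relabelling", {
  vals <- sapply(1:10, function(s) {
    set.seed(s)
    a <- matrix(runif(64 * 64), 64, 64)
    set.seed(s + 1000)
    b <- matrix(runif(64 * 64), 64, 64)
    cube <- hyper_cube(array(c(a, b, a, b), c(64, 64, 4)),
                       wavelength_grid(n_bands = 4))
    mi_matrix(cube)[1, 2]
  })
  expect_lt(mean(vals), 0.2)
  # a strictly increasing bin-preserving relabelling leaves the score unchanged
  set.seed(7)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  relab <- (floor(pmin(a, 1 - 1e-12) * 64) + 0.5) / 64   # maps each bin to its centre
  cube1 <- hyper_cube(array(c(a, b, a, b), c(32, 32, 4)), wavelength_grid(n_bands = 4))
  cube2 <- hyper_cube(array(c(relab, b, a, b), c(32, 32, 4)), wavelength_grid(n_bands = 4))
  expect_equal(mi_matrix(cube1)[1, 2], mi_matrix(cube2)[1, 2])
})

test_that("SSIM matches the independent reference value on a fixed pair", {
  fx <- ssim_fixture()
  cube <- hyper_cube(array(c(fx$a, fx$b, fx$a, fx$b), c(24, 24, 4)),
                     wavelength_grid(n_bands = 4))
  S <- ssim_matrix(cube)
  # reference: scikit-image structural_similarity, Gaussian window 11,
  # sigma 1.5, K1=0.01, K2=0.03, data_range 1, population covariance
  expect_equal(S[1, 2], 0.8818938560486055, tolerance = 1e-6)
  shifted <- pmin(fx$a + 0.5, 1)
  cube2 <- hyper_cube(array(c(fx$a, shifted, fx$a, fx$b), c(24, 24, 4)),
                      wavelength_grid(n_bands = 4))
  expect_lt(ssim_matrix(cube2)[1, 2], 1)
})

test_that("combine normalizes per metric and respects the weights", {
  set.seed(3)
  M <- matrix(runif(25, 0.2, 0.8), 5, 5); M <- (M + t(M)) / 2; diag(M) <- 1
  ms <- lapply(1:4, function(i) M)
  comb <- combine_similarity(ms)
  off <- !diag(TRUE, 5)
  Mn <- M; Mn[off] <- (M[off] - min(M[off])) / (max(M[off]) - min(M[off]))
  diag(Mn) <- 1
  expect_equal(unclass(comb), Mn, ignore_attr = TRUE)
  # weights (1,0,0,0) reduce to the first normalized matrix
  M2 <- matrix(runif(25, 0, 1), 5, 5); M2 <- (M2 + t(M2)) / 2; diag(M2) <- 1
  comb2 <- combine_similarity(list(M, M2, M2, M2), c(1, 0, 0, 0))
  expect_equal(unclass(comb2), Mn, ignore_attr = TRUE)
  # hand-computed 3x3 weighted sum
  A <- matrix(c(1, .2, .6, .2, 1, .4, .6, .4, 1), 3, 3)
  B <- matrix(c(1, .9, .1, .9, 1, .5, .1, .5, 1), 3, 3)
  cw <- combine_similarity(list(A, B, A, B), c(.5, .5, 0, 0))
  An <- (A - .2) / .4; Bn <- (B - .1) / .8
  expect_equal(cw[1, 2], .5 * An[1, 2] + .5 * Bn[1, 2])
  expect_equal(cw[1, 3], .5 * An[1, 3] + .5 * Bn[1, 3])
  # constant off-diagonal metric contributes 0.5
  Cst <- matrix(0.7, 3, 3); diag(Cst) <- 1
  cc <- combine_similarity(list(Cst, Cst, Cst, Cst))
  expect_equal(cc[1, 2], 0.5)
  d <- difference_matrix(cw)
  expect_equal(as.vector(diag(d)), rep(0, 3))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("Max-Min greedy reproduces the hand-traced example", {
  D <- matrix(c(0, .9, .2, .5,
                .9, 0, .4, .1,
                .2, .4, 0, .7,
                .5, .1, .7, 0), 4, 4, byrow = TRUE)
  expect_equal(maxmin_select(D, 1:4, 3), c(1L, 2L, 3L))
  expect_equal(maxmin_select(D, 1:4, 1), 1L)
  expect_error(maxmin_select(D, integer(0), 1), "empty")
})

test_that("every greedy step attains the step optimum (exhaustive oracle)", {
  for (s in 1:6) {
    set.seed(s)
    B <- sample(5:16, 1)
    D <- matrix(runif(B * B), B, B); D <- (D + t(D)) / 2; diag(D) <- 0
    k <- sample(2:min(6, B), 1)
    sel <- maxmin_select(D, 1:B, k)
    # step 1: row-sum maximizer
    expect_equal(sel[1], which.max(rowSums(D)))
    for (step in 2:k) {
      omega <- sel[1:(step - 1)]
      cand <- setdiff(1:B, omega)
      md <- vapply(cand, function(b) min(D[b, omega]), numeric(1))
      expect_equal(min(D[sel[step], omega]), max(md))
    }
  }
})

test_that("Strategy A fills the 3:3:4 segment quotas on a 128-band grid", {
  cube <- toy_cube(16, 16, 4)
  set.seed(8)
  B <- 128
  D <- matrix(runif(B * B), B, B); D <- (D + t(D)) / 2; diag(D) <- 0
  wl <- wavelength_grid()
  bs <- strategy_a(D, wl)
  expect_equal(bs$k, 10L)
  expect_equal(length(unique(bs$bands)), 10L)
  seg <- spectral_segments(wl)[bs$bands]
  expect_equal(as.vector(table(seg)), c(3L, 3L, 4L))
  expect_false(is.unsorted(bs$bands))
})

test_that("Strategy B applies the coverage reward as hand-traced", {
  D <- matrix(c(0, .9, .2, .5,
                .9, 0, .4, .1,
                .2, .4, 0, .7,
                .5, .1, .7, 0), 4, 4, byrow = TRUE)
  # regions VIS VIS RED NIR via a fake 4-point wavelength grid
  wl <- c(400, 500, 650, 800); class(wl) <- "wavelength_grid"
  bs <- strategy_b(D, wl, lambda_cov = 0.5, k = 3)
  expect_equal(bs$bands, c(1L, 2L, 3L))
  # lambda_cov = 0 reduces to plain global Max-Min
  bs0 <- strategy_b(D, wl, lambda_cov = 0, k = 3)
  expect_equal(bs0$bands, maxmin_select(D, 1:4, 3))
  expect_error(strategy_b(D, wl, lambda_cov = -0.1, k = 2), "lambda_cov")
})

test_that("a large coverage reward covers all regions within three picks", {
  wl <- wavelength_grid()
  for (s in 1:3) {
    set.seed(s)
    D <- matrix(runif(128^2), 128, 128); D <- (D + t(D)) / 2; diag(D) <- 0
    bs <- strategy_b(D, wl, lambda_cov = 10, k = 10)
    expect_equal(length(unique(bs$bands)), 10L)
    seg3 <- spectral_segments(wl)[bs$bands[1:3]]
    expect_setequal(as.character(seg3), c("VIS", "RED", "NIR"))
  }
})
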