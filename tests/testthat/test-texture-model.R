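test_that("the stem emits 384 channels at unchanged resolution with SE gates in (0,1)", {
  set.seed(81)
  stack <- array(runif(24 * 24 * 12), c(24, 24, 12))
  out <- texture_stem(stack)                 # reference configuration
  expect_equal(dim(out), c(24L, 24L, 384L))
  gates <- attr(out, "se_gate")
  expect_length(gates, 64L)
  expect_true(all(gates > 0 & gates < 1))
  # channel-symmetric features + channel-symmetric SE weights => equal gates
  cfg <- texture_config(in_ch = 4L, mix = 8L, embed = 16L, se_ratio = 2L,
                        heads = 4L)
  p <- xylospec:::texture_init(cfg, 2)
  p$Wc1 <- p$Wc1[, rep(1, 8)]          # every mixed channel computes the same map
  p$bc1 <- rep(p$bc1[1], 8)
  p$Wdw <- p$Wdw[, rep(1, 8)]; p$bdw <- rep(0, 8)
  p$Wse2 <- p$Wse2[, rep(1, 8)]; p$bse2 <- rep(0, 8)
  A <- array(runif(16 * 16 * 4), c(16, 16, 4, 1))
  st <- xylospec:::stem_forward(p, cfg, A, xylospec:::texture_state_init(cfg),
                                train = TRUE)
  expect_lt(diff(range(st$gate)), 1e-12)
  expect_error(texture_stem(array(0, c(16, 16, 5))), "channels")
})

test_that("head grouping maps h mod 4 onto the four modalities", {
  expect_equal(head_modality(0), "fusion")
  expect_equal(head_modality(5), "sobel")
  expect_equal(head_modality(7), "gabor")
  expect_equal(head_modality(2), "moments")
  # surjective whenever heads >= 4
  for (H in 4:9) expect_setequal(head_modality(0:(H - 1)),
                                 c("fusion", "sobel", "moments", "gabor"))
  expect_error(head_modality(-1), ">= 0")
})

test_that("True-Score selection balances confidence and dispersion", {
  pts <- structure(data.frame(x = c(0, 0, 30), y = c(0, 1, 40),
                              score = c(0.9, 0.9, 0.5)),
                   class = c("interest_points", "data.frame"))
  # alpha = 1: pure confidence, order by score
  t1 <- true_score_select(pts, alpha = 1, L = 10, n_keep = 3)
  expect_equal(t1$true_score[1], 0.9)
  # one selected point at distance exactly L: diversity term is exactly 1
  p2 <- structure(data.frame(x = c(0, 10), y = c(0, 0), score = c(0.9, 0.6)),
                  class = c("interest_points", "data.frame"))
  t2 <- true_score_select(p2, alpha = 0.7, L = 10, n_keep = 2)
  expect_equal(t2$true_score[2], 0.7 * 0.6 + 0.3 * 1)
  # coincident vs far candidate with equal scores: far one wins
  p3 <- structure(data.frame(x = c(5, 5, 50), y = c(5, 5, 50),
                             score = c(0.8, 0.6, 0.6)),
                  class = c("interest_points", "data.frame"))
  t3 <- true_score_select(p3, alpha = 0.7, L = 20, n_keep = 3)
  expect_equal(t3$x[2], 50)
  expect_error(true_score_select(pts, L = -1), "L must be")
})

test_that("saliency projection floors to the token grid and keeps maxima", {
  pts <- data.frame(x = 9, y = 5, score = 0.8, true_score = 0.8)
  H <- saliency_map(pts, 4, c(4, 4))
  expect_equal(which(H > 0), 2L + 4L * 2L)   # (ty, tx) = (1, 2) 0-based, column-major
  expect_equal(H[2, 3], 0.8)
  # collision resolves by max
  pts2 <- data.frame(x = c(1, 2), y = c(1, 2), score = c(0.4, 0.7),
                     true_score = c(0.4, 0.7))
  H2 <- saliency_map(pts2, 4, c(2, 2))
  expect_equal(H2[1, 1], 0.7)
  expect_equal(saliency_map(pts2[0, ], 4, c(2, 2)), matrix(0, 2, 2))
  expect_error(saliency_map(pts, 0, c(2, 2)), "stride")
})

test_that("zero saliency reproduces unbiased windowed attention bitwise", {
  cfg <- texture_config(in_ch = 3, mix = 6, embed = 8, se_ratio = 2,
                        patch = 2, window = 2, heads = 4, depth = 2,
                        n_classes = 3)
  p <- xylospec:::texture_init(cfg, 12)
  state <- xylospec:::texture_state_init(cfg)
  set.seed(12)
  stacks <- lapply(1:2, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  zero_sal <- lapply(1:2, function(i)
    list(fusion = matrix(0, 4, 4), sobel = matrix(0, 4, 4),
         moments = matrix(0, 4, 4), gabor = matrix(0, 4, 4)))
  l_zero <- xylospec:::texture_forward(p, cfg, stacks, zero_sal, state)$logits
  l_null <- xylospec:::texture_forward(p, cfg, stacks, vector("list", 2), state)$logits
  expect_identical(l_zero, l_null)
  # non-zero saliency changes the logits
  sal <- zero_sal
  sal[[1]]$gabor[2, 2] <- 1
  l_sal <- xylospec:::texture_forward(p, cfg, stacks, sal, state)$logits
  expect_gt(max(abs(l_sal - l_zero)), 0)
  # eval determinism
  expect_identical(xylospec:::texture_forward(p, cfg, stacks, sal, state)$logits,
                   l_sal)
  # constant shift of every token's saliency leaves attention unchanged
  sal_shift <- lapply(sal, function(s) lapply(s, function(m) m + 0.37))
  l_shift <- xylospec:::texture_forward(p, cfg, stacks, sal_shift, state)$logits
  expect_equal(l_shift, l_sal, tolerance = 1e-10)
})

test_that("raising one key's saliency raises its attention weight for every query", {
  set.seed(9)
  T_ <- 6; d <- 8
  X <- matrix(rnorm(T_ * d), T_, d)
  Wqkv <- matrix(rnorm(d * 3 * d, 0, 0.3), d, 3 * d)
  Wo <- diag(d)
  base_bias <- matrix(0, T_, T_)
  up_bias <- base_bias; up_bias[, 4] <- 1     # key 4 more salient
  a0 <- xylospec:::mha_forward(X, Wqkv, numeric(3 * d), Wo, numeric(d), 2,
                               bias = base_bias)
  a1 <- xylospec:::mha_forward(X, Wqkv, numeric(3 * d), Wo, numeric(d), 2,
                               bias = up_bias)
  for (h in 1:2) expect_true(all(a1$cache$A[[h]][, 4] > a0$cache$A[[h]][, 4]))
})

test_that("texture gradients match finite differences", {
  cfg <- texture_config(in_ch = 3, mix = 4, embed = 8, se_ratio = 2,
                        patch = 2, window = 2, heads = 4, depth = 2,
                        n_classes = 3)
  p <- xylospec:::texture_init(cfg, 3)
  state <- xylospec:::texture_state_init(cfg)
  set.seed(3)
  stacks <- lapply(1:2, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  sal <- lapply(1:2, function(i)
    list(fusion = matrix(runif(16, 0, .5), 4, 4),
         sobel = matrix(runif(16, 0, .5), 4, 4),
         moments = matrix(runif(16, 0, .5), 4, 4),
         gabor = matrix(runif(16, 0, .5), 4, 4)))
  y <- c(1L, 3L)
  fw <- xylospec:::texture_forward(p, cfg, stacks, sal, state, train = TRUE)
  ce <- xylospec:::cross_entropy(fw$logits, y)
  gr <- xylospec:::texture_backward(p, cfg, fw$cache, ce$dlogits)
  lossfun <- function(params) {
    f <- xylospec:::texture_forward(params, cfg, stacks, sal, state, train = TRUE)
    xylospec:::cross_entropy(f$logits, y)$loss
  }
  eps <- 1e-5
  for (nm in c("Wc1", "Wdw", "Wse2", "Wc2", "l1_Wqkv", "l1_rpb", "l2_W1",
               "bn1_g", "W_head")) {
    set.seed(match(nm, names(p)))
    for (k in 1:2) {
      i <- sample(length(p[[nm]]), 1)
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("texture training learns a separable two-class texture problem", {
  set.seed(91)
  mk <- function(freq, n) lapply(1:n, function(i) {
    base <- 0.5 + 0.4 * sin(2 * pi * freq * outer(1:24, 1:24, `+`) / 100 +
                            runif(1, 0, 2 * pi))
    array(rep(base, 3) + rnorm(24 * 24 * 3, 0, 0.02), c(24, 24, 3))
  })
  stacks <- c(mk(6, 8), mk(18, 8))
  y <- rep(1:2, each = 8)
  cfg <- texture_config(in_ch = 3, mix = 8, embed = 16, se_ratio = 2,
                        patch = 4, window = 3, heads = 4, depth = 2,
                        n_classes = 2)
  m <- train_texture(stacks, NULL, y, cfg, epochs = 12, batch_size = 4,
                     lr = 3e-3, seed = 2) |> suppressWarnings()
  expect_lt(m$history[length(m$history)], m$history[1])
  pred <- predict(m, stacks)
  expect_gte(mean(pred == y), 0.9)
  m2 <- train_texture(stacks, NULL, y, cfg, epochs = 2, batch_size = 4,
                      lr = 3e-3, seed = 5) |> suppressWarnings()
  m3 <- train_texture(stacks, NULL, y, cfg, epochs = 2, batch_size = 4,
                      lr = 3e-3, seed = 5) |> suppressWarnings()
  expect_identical(m2$params, m3$params)
})
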