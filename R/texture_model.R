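# Texture branch: a convolutional Texture Stem (12 -> 64 -> 64 -> embed
# channels with squeeze-excitation recalibration) feeding a windowed-
# attention transformer whose heads are grouped by texture modality and
# biased by sparse interest-point saliency maps (MG-GMH).

# ---- batched array helpers (A is H x W x C x n) ------------------------

arr2mat <- function(A) {
  d <- dim(A)
  dim_a <- aperm(A, c(1, 2, 4, 3))
  matrix(dim_a, d[1] * d[2] * d[4], d[3])
}

mat2arr <- function(M, H, W, n, C) {
  aperm(array(M, c(H, W, n, C)), c(1, 2, 4, 3))
}

shift4 <- function(A, dr, dc) {
  d <- dim(A)
  out <- array(0, d)
  r_src <- max(1, 1 - dr):min(d[1], d[1] - dr)
  c_src <- max(1, 1 - dc):min(d[2], d[2] - dc)
  out[r_src + dr, c_src + dc, , ] <- A[r_src, c_src, , , drop = FALSE]
  out
}

conv3_offsets <- expand.grid(dr = -1:1, dc = -1:1)

# 3x3 convolution (zero padding) as 9 shifted matmuls; W is (9*Cin) x Cout
conv3_forward <- function(A, W, b) {
  d <- dim(A); Cin <- d[3]
  HWn <- d[1] * d[2] * d[4]
  Cout <- ncol(W)
  Y <- matrix(rep(b, each = HWn), HWn, Cout)
  Xc <- matrix(0, HWn, 9 * Cin)
  for (k in 1:9) {
    sh <- shift4(A, conv3_offsets$dr[k], conv3_offsets$dc[k])
    Xc[, ((k - 1) * Cin + 1):(k * Cin)] <- arr2mat(sh)
  }
  Y <- Y + Xc %*% W
  list(out = mat2arr(Y, d[1], d[2], d[4], Cout), Xc = Xc, dim_in = d)
}

conv3_backward <- function(dY_arr, cache, W) {
  d <- cache$dim_in; Cin <- d[3]
  dY <- arr2mat(dY_arr)
  dW <- crossprod(cache$Xc, dY)
  db <- colSums(dY)
  dXc <- tcrossprod(dY, W)
  dA <- array(0, d)
  for (k in 1:9) {
    piece <- mat2arr(dXc[, ((k - 1) * Cin + 1):(k * Cin), drop = FALSE],
                     d[1], d[2], d[4], Cin)
    dA <- dA + shift4(piece, -conv3_offsets$dr[k], -conv3_offsets$dc[k])
  }
  list(dA = dA, dW = dW, db = db)
}

# depthwise 3x3 convolution; w is 9 x C
dwconv3_forward <- function(A, w, b) {
  d <- dim(A)
  Y <- array(rep(rep(b, each = d[1] * d[2]), d[4]), d)
  shifts <- vector("list", 9)
  for (k in 1:9) {
    sh <- shift4(A, conv3_offsets$dr[k], conv3_offsets$dc[k])
    shifts[[k]] <- sh
    Y <- Y + sweep(sh, 3, w[k, ], `*`)
  }
  list(out = Y, shifts = shifts, dim_in = d)
}

dwconv3_backward <- function(dY, cache, w) {
  d <- cache$dim_in
  dw <- matrix(0, 9, d[3])
  dA <- array(0, d)
  for (k in 1:9) {
    dw[k, ] <- colSums(arr2mat(cache$shifts[[k]] * dY))
    dA <- dA + shift4(sweep(dY, 3, w[k, ], `*`),
                      -conv3_offsets$dr[k], -conv3_offsets$dc[k])
  }
  db <- colSums(arr2mat(dY))
  list(dA = dA, dw = dw, db = db)
}

# batch norm over rows of an (HWn x C) matrix
bn_forward <- function(M, g, b, run_mean, run_var, train, momentum = 0.1,
                       eps = 1e-5) {
  if (train) {
    mu <- colMeans(M)
    xc <- sweep(M, 2, mu)
    v <- colMeans(xc * xc)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
    xc <- sweep(M, 2, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(out = out, xhat = xhat, inv = inv, run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  n <- nrow(dY)
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  dX <- sweep(dxhat - rep(1, n) %o% colMeans(dxhat) -
              xhat * (rep(1, n) %o% colMeans(dxhat * xhat)), 2, inv, `*`)
  list(dX = dX, dg = dg, db = db)
}

# ---- configuration -----------------------------------------------------

#' Configuration for the texture branch
#'
#' @param in_ch Input channels (12: fusion 1 + Sobel 2 + moments 3 + Gabor 6).
#' @param mix Stem mixing width (64).
#' @param embed Token embedding width after the stem (384 in the reference
#'   setting; configurable for small-scale runs).
#' @param se_ratio Squeeze-excitation bottleneck reduction.
#' @param patch Token patch stride p.
#' @param window Attention window side.
#' @param heads Attention heads (>= 4 so the modality grouping is
#'   surjective).
#' @param depth Transformer depth (shifted windows on alternate blocks).
#' @param mlp_ratio MLP widening factor.
#' @param n_classes Number of species.
#' @return A `texture_config` list.
#' @export
texture_config <- function(in_ch = 12L, mix = 64L, embed = 384L, se_ratio = 16L,
                           patch = 4L, window = 7L, heads = 8L, depth = 4L,
                           mlp_ratio = 2, n_classes = 10L) {
  if (heads < 4L) stop("heads must be >= 4 so every modality guides a head")
  if (embed %% heads != 0) stop("heads must divide embed")
  structure(list(in_ch = as.integer(in_ch), mix = as.integer(mix),
                 embed = as.integer(embed), se_ratio = as.integer(se_ratio),
                 patch = as.integer(patch), window = as.integer(window),
                 heads = as.integer(heads), depth = as.integer(depth),
                 mlp_ratio = mlp_ratio, n_classes = as.integer(n_classes)),
            class = "texture_config")
}

#' Texture modality guiding an attention head
#'
#' Head index (0-based) maps to a modality by `h mod 4`:
#' 0 = Fusion, 1 = Sobel, 2 = Moments, 3 = Gabor.
#'
#' @param h Non-negative head index (vectorised).
#' @return Character modality name(s).
#' @export
head_modality <- function(h) {
  if (any(h < 0)) stop("head index must be >= 0")
  c("fusion", "sobel", "moments", "gabor")[(h %% 4) + 1]
}

texture_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    E <- cfg$embed; mix <- cfg$mix
    se_mid <- max(1L, mix %/% cfg$se_ratio)
    p <- list(
      Wc1 = init_mat(9 * cfg$in_ch, mix, sd = 0.05), bc1 = numeric(mix),
      bn1_g = rep(1, mix), bn1_b = numeric(mix),
      Wdw = init_mat(9, mix, sd = 0.1), bdw = numeric(mix),
      bn2_g = rep(1, mix), bn2_b = numeric(mix),
      Wse1 = init_mat(mix, se_mid, sd = 0.1), bse1 = numeric(se_mid),
      Wse2 = init_mat(se_mid, mix, sd = 0.1), bse2 = numeric(mix),
      Wc2 = init_mat(mix, E, sd = 0.02), bc2 = numeric(E))
    nrpb <- (2 * cfg$window - 1)^2
    for (l in seq_len(cfg$depth)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, E)
      p[[paste0(pre, "ln1_b")]] <- numeric(E)
      p[[paste0(pre, "Wqkv")]] <- init_mat(E, 3 * E)
      p[[paste0(pre, "bqkv")]] <- numeric(3 * E)
      p[[paste0(pre, "Wo")]] <- init_mat(E, E)
      p[[paste0(pre, "bo")]] <- numeric(E)
      p[[paste0(pre, "rpb")]] <- init_mat(nrpb, cfg$heads)
      p[[paste0(pre, "ln2_g")]] <- rep(1, E)
      p[[paste0(pre, "ln2_b")]] <- numeric(E)
      p[[paste0(pre, "W1")]] <- init_mat(E, round(E * cfg$mlp_ratio))
      p[[paste0(pre, "b1")]] <- numeric(round(E * cfg$mlp_ratio))
      p[[paste0(pre, "W2")]] <- init_mat(round(E * cfg$mlp_ratio), E)
      p[[paste0(pre, "b2")]] <- numeric(E)
    }
    p$ln_f_g <- rep(1, E); p$ln_f_b <- numeric(E)
    p$W_head <- init_mat(E, cfg$n_classes)
    p$b_head <- numeric(cfg$n_classes)
    p
  })
}

texture_state_init <- function(cfg) {
  list(bn1_mean = numeric(cfg$mix), bn1_var = rep(1, cfg$mix),
       bn2_mean = numeric(cfg$mix), bn2_var = rep(1, cfg$mix))
}

# ---- Texture Stem ------------------------------------------------------

# stacks: H x W x 12 x n array; returns tokens-before-pooling feature array
# (H x W x E x n) plus caches; `state` holds BN running stats.
stem_forward <- function(params, cfg, A, state, train = FALSE) {
  d <- dim(A)
  c1 <- conv3_forward(A, params$Wc1, params$bc1)
  M1 <- arr2mat(c1$out)
  bn1 <- bn_forward(M1, params$bn1_g, params$bn1_b, state$bn1_mean,
                    state$bn1_var, train)
  state$bn1_mean <- bn1$run_mean; state$bn1_var <- bn1$run_var
  G1 <- gelu(bn1$out)
  X1 <- mat2arr(G1, d[1], d[2], d[4], cfg$mix)
  dw <- dwconv3_forward(X1, params$Wdw, params$bdw)
  M2 <- arr2mat(dw$out)
  bn2 <- bn_forward(M2, params$bn2_g, params$bn2_b, state$bn2_mean,
                    state$bn2_var, train)
  state$bn2_mean <- bn2$run_mean; state$bn2_var <- bn2$run_var
  G2 <- gelu(bn2$out)
  X2 <- mat2arr(G2, d[1], d[2], d[4], cfg$mix)
  # squeeze-excitation: GAP per channel and sample -> bottleneck -> gate
  Sm <- t(matrix(colMeans(matrix(X2, d[1] * d[2], cfg$mix * d[4])), cfg$mix, d[4]))
  Z1 <- linear_forward(Sm, params$Wse1, params$bse1)
  R1 <- pmax(Z1, 0)
  Z2 <- linear_forward(R1, params$Wse2, params$bse2)
  gate <- sigmoid(Z2)                      # n x mix, strictly in (0,1)
  gate_arr <- aperm(array(rep(t(gate), each = d[1] * d[2]),
                          c(d[1], d[2], cfg$mix, d[4])), c(1, 2, 3, 4))
  X3 <- X2 * gate_arr
  M3 <- arr2mat(X3)
  Y <- linear_forward(M3, params$Wc2, params$bc2)
  out <- mat2arr(Y, d[1], d[2], d[4], cfg$embed)
  list(out = out, state = state, gate = gate,
       cache = list(c1 = c1, bn1 = bn1, M1 = M1, dw = dw, bn2 = bn2, M2 = M2,
                    X1 = X1, X2 = X2, Sm = Sm, Z1 = Z1, R1 = R1, Z2 = Z2,
                    gate = gate, gate_arr = gate_arr, M3 = M3, dim_in = d))
}

stem_backward <- function(params, cfg, cache, dOut) {
  d <- cache$dim_in
  dY <- arr2mat(dOut)
  g <- list()
  g$Wc2 <- crossprod(cache$M3, dY)
  g$bc2 <- colSums(dY)
  dM3 <- tcrossprod(dY, params$Wc2)
  dX3 <- mat2arr(dM3, d[1], d[2], d[4], cfg$mix)
  dX2_direct <- dX3 * cache$gate_arr
  # gate gradient: sum over pixels of dX3 * X2 per (sample, channel)
  prod_arr <- dX3 * cache$X2
  dgate <- t(matrix(colSums(matrix(prod_arr, d[1] * d[2], cfg$mix * d[4])),
                    cfg$mix, d[4]))
  dZ2 <- dgate * cache$gate * (1 - cache$gate)
  g$Wse2 <- crossprod(cache$R1, dZ2)
  g$bse2 <- colSums(dZ2)
  dR1 <- tcrossprod(dZ2, params$Wse2)
  dZ1 <- dR1 * (cache$Z1 > 0)
  g$Wse1 <- crossprod(cache$Sm, dZ1)
  g$bse1 <- colSums(dZ1)
  dSm <- tcrossprod(dZ1, params$Wse1)
  # GAP backward: spread dSm / (H*W) over pixels
  dX2_gap <- aperm(array(rep(t(dSm / (d[1] * d[2])), each = d[1] * d[2]),
                         c(d[1], d[2], cfg$mix, d[4])), c(1, 2, 3, 4))
  dX2 <- dX2_direct + dX2_gap
  dG2 <- arr2mat(dX2)
  dBn2out <- dG2 * gelu_grad(cache$bn2$out)
  bb2 <- bn_backward(dBn2out, cache$bn2, params$bn2_g)
  g$bn2_g <- bb2$dg; g$bn2_b <- bb2$db
  dDw <- mat2arr(bb2$dX, d[1], d[2], d[4], cfg$mix)
  dwb <- dwconv3_backward(dDw, cache$dw, params$Wdw)
  g$Wdw <- dwb$dw; g$bdw <- dwb$db
  dG1 <- arr2mat(dwb$dA)
  dBn1out <- dG1 * gelu_grad(cache$bn1$out)
  bb1 <- bn_backward(dBn1out, cache$bn1, params$bn1_g)
  g$bn1_g <- bb1$dg; g$bn1_b <- bb1$db
  dC1 <- mat2arr(bb1$dX, d[1], d[2], d[4], cfg$in_ch * 0 + cfg$mix)
  cb <- conv3_backward(dC1, cache$c1, params$Wc1)
  g$Wc1 <- cb$dW; g$bc1 <- cb$db
  g
}

#' Run the Texture Stem on a 12-channel stack
#'
#' Exposes the convolutional front end on its own: 3x3 conv (12 -> 64) +
#' BN + GELU, depthwise 3x3 + BN + GELU, squeeze-excitation channel
#' recalibration, and a 1x1 conv to the embedding width. Spatial resolution
#' is preserved.
#'
#' @param stack H x W x 12 array (a `texture_stack`).
#' @param cfg A [texture_config()].
#' @param seed Seed for the randomly initialized weights.
#' @return H x W x embed array; the SE gate values are attached as
#'   attribute `"se_gate"`.
#' @export
texture_stem <- function(stack, cfg = texture_config(), seed = 1L) {
  if (dim(stack)[3] != cfg$in_ch) stop("stack must have ", cfg$in_ch, " channels")
  params <- texture_init(cfg, seed)
  A <- array(stack, c(dim(stack)[1], dim(stack)[2], cfg$in_ch, 1))
  st <- stem_forward(params, cfg, A, texture_state_init(cfg), train = TRUE)
  out <- st$out[, , , 1]
  attr(out, "se_gate") <- st$gate[1, ]
  out
}

# ---- window attention --------------------------------------------------

# relative-position-bias index for a w x w window: (w^2 x w^2) into the
# (2w-1)^2 table
rpb_index <- function(w) {
  coords <- expand.grid(r = 0:(w - 1), c = 0:(w - 1))
  dr <- outer(coords$r, coords$r, "-") + (w - 1)
  dc <- outer(coords$c, coords$c, "-") + (w - 1)
  dr * (2 * w - 1) + dc + 1
}

# partition metadata for a (possibly padded, possibly shifted) token grid
window_layout <- function(Ht, Wt, w, shift) {
  Hp <- ceiling(Ht / w) * w
  Wp <- ceiling(Wt / w) * w
  valid <- matrix(FALSE, Hp, Wp); valid[1:Ht, 1:Wt] <- TRUE
  region <- matrix(0L, Hp, Wp)
  if (shift > 0) {
    rid <- function(n) {
      id <- integer(n)
      id[] <- 0L
      if (n - w + 1 <= n) id[max(1, n - w + 1):n] <- 1L
      if (n - shift + 1 <= n) id[max(1, n - shift + 1):n] <- 2L
      id
    }
    region <- outer(rid(Hp) * 3L, rid(Wp), `+`)
  }
  roll <- function(M, s) {
    if (s == 0) return(M)
    M[((seq_len(nrow(M)) - 1 + s) %% nrow(M)) + 1,
      ((seq_len(ncol(M)) - 1 + s) %% ncol(M)) + 1, drop = FALSE]
  }
  valid_s <- roll(valid, shift)
  region_s <- roll(region, shift)
  nwr <- Hp / w; nwc <- Wp / w
  windows <- list()
  k <- 0
  lin <- matrix(seq_len(Hp * Wp), Hp, Wp)      # linear index into shifted grid
  for (wi in seq_len(nwr)) for (wj in seq_len(nwc)) {
    rows <- ((wi - 1) * w + 1):(wi * w)
    cols <- ((wj - 1) * w + 1):(wj * w)
    idx <- as.vector(lin[rows, cols])
    v <- as.vector(valid_s[rows, cols])
    reg <- as.vector(region_s[rows, cols])
    mask <- matrix(0, w * w, w * w)
    bad <- outer(reg, reg, `!=`) | matrix(!v, w * w, w * w, byrow = TRUE)
    mask[bad] <- -1e9
    k <- k + 1
    windows[[k]] <- list(idx = idx, valid = v, mask = mask)
  }
  list(Hp = Hp, Wp = Wp, windows = windows, shift = shift)
}

# map padded+shifted linear index back to original token index (or NA)
shifted_token_map <- function(Ht, Wt, Hp, Wp, shift) {
  orig <- matrix(NA_integer_, Hp, Wp)
  orig[1:Ht, 1:Wt] <- matrix(seq_len(Ht * Wt), Ht, Wt)
  if (shift > 0) {
    orig <- orig[((seq_len(Hp) - 1 + shift) %% Hp) + 1,
                 ((seq_len(Wp) - 1 + shift) %% Wp) + 1, drop = FALSE]
  }
  as.vector(orig)
}

# ---- full forward / backward ------------------------------------------

# tokens: T x E matrix per sample (T = Ht*Wt); sal: list of 4 token-grid
# saliency matrices (Ht x Wt) or NULL
texture_forward <- function(params, cfg, stacks, saliency = NULL, state,
                            train = FALSE) {
  n <- length(stacks)
  d1 <- dim(stacks[[1]])
  A <- array(0, c(d1[1], d1[2], cfg$in_ch, n))
  for (i in seq_len(n)) A[, , , i] <- stacks[[i]]
  st <- stem_forward(params, cfg, A, state, train)
  state <- st$state
  p <- cfg$patch
  Ht <- d1[1] %/% p; Wt <- d1[2] %/% p
  E <- cfg$embed
  # p x p mean pooling to tokens (reshape trick: split H into (p, Ht))
  Tok <- vector("list", n)
  Ar <- array(st$out[seq_len(Ht * p), seq_len(Wt * p), , , drop = FALSE],
              c(p, Ht, p, Wt, E, n))
  Ap <- aperm(Ar, c(1, 3, 2, 4, 5, 6))
  pooled <- array(colMeans(matrix(Ap, p * p)), c(Ht, Wt, E, n))
  for (i in seq_len(n)) Tok[[i]] <- matrix(pooled[, , , i], Ht * Wt, E)
  w <- cfg$window
  rpb_idx <- rpb_index(w)
  layer_caches <- vector("list", cfg$depth)
  layouts <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("l", l, "_")
    shift <- if (l %% 2 == 0) w %/% 2 else 0
    lay <- window_layout(Ht, Wt, w, shift)
    layouts[[l]] <- lay
    tmap <- shifted_token_map(Ht, Wt, lay$Hp, lay$Wp, shift)
    sample_caches <- vector("list", n)
    for (i in seq_len(n)) {
      X <- Tok[[i]]
      ln1 <- ln_forward(X, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
      att <- matrix(0, Ht * Wt, E)
      wcaches <- vector("list", length(lay$windows))
      for (wk in seq_along(lay$windows)) {
        win <- lay$windows[[wk]]
        orig <- tmap[win$idx]
        Xw <- matrix(0, w * w, E)
        Xw[!is.na(orig), ] <- ln1$out[orig[!is.na(orig)], , drop = FALSE]
        bias <- vector("list", cfg$heads)
        for (h in seq_len(cfg$heads)) {
          bh <- params[[paste0(pre, "rpb")]][rpb_idx, h]
          dim(bh) <- dim(rpb_idx)
          bh <- bh + win$mask
          if (!is.null(saliency) && !is.null(saliency[[i]])) {
            m <- head_modality(h - 1)
            sal <- saliency[[i]][[m]]
            if (!is.null(sal)) {
              sv <- numeric(w * w)
              sv[!is.na(orig)] <- as.vector(sal)[orig[!is.na(orig)]]
              bh <- bh + matrix(sv, w * w, w * w, byrow = TRUE)
            }
          }
          bias[[h]] <- bh
        }
        mh <- mha_forward(Xw, params[[paste0(pre, "Wqkv")]], params[[paste0(pre, "bqkv")]],
                          params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]],
                          cfg$heads, bias = bias)
        ok <- !is.na(orig)
        att[orig[ok], ] <- mh$out[ok, , drop = FALSE]
        wcaches[[wk]] <- list(cache = mh$cache, orig = orig)
      }
      X1 <- X + att
      ln2 <- ln_forward(X1, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
      H1 <- linear_forward(ln2$out, params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
      G <- gelu(H1)
      M <- linear_forward(G, params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
      Tok[[i]] <- X1 + M
      sample_caches[[i]] <- list(ln1 = ln1, wins = wcaches, X = X, X1 = X1,
                                 ln2 = ln2, H1 = H1, G = G)
    }
    layer_caches[[l]] <- sample_caches
  }
  P <- matrix(0, n, E)
  lnf_caches <- vector("list", n)
  for (i in seq_len(n)) {
    lnf <- ln_forward(Tok[[i]], params$ln_f_g, params$ln_f_b)
    lnf_caches[[i]] <- lnf
    P[i, ] <- colMeans(lnf$out)
  }
  logits <- linear_forward(P, params$W_head, params$b_head)
  cache <- if (train) list(stem = st$cache, pooled_dim = c(Ht, Wt, E, n),
                           layers = layer_caches, layouts = layouts,
                           lnf = lnf_caches, P = P, rpb_idx = rpb_idx,
                           tmaps = lapply(seq_len(cfg$depth), function(l)
                             shifted_token_map(Ht, Wt, layouts[[l]]$Hp,
                                               layouts[[l]]$Wp, layouts[[l]]$shift)),
                           stack_dim = d1) else NULL
  list(logits = logits, cache = cache, state = state)
}

texture_backward <- function(params, cfg, cache, dlogits) {
  n <- nrow(dlogits)
  E <- cfg$embed
  Ht <- cache$pooled_dim[1]; Wt <- cache$pooled_dim[2]
  T_ <- Ht * Wt
  g <- list()
  g$W_head <- crossprod(cache$P, dlogits)
  g$b_head <- colSums(dlogits)
  dP <- tcrossprod(dlogits, params$W_head)
  dTok <- vector("list", n)
  for (i in seq_len(n)) {
    dF <- matrix(dP[i, ] / T_, T_, E, byrow = TRUE)
    lb <- ln_backward(dF, cache$lnf[[i]], params$ln_f_g)
    g$ln_f_g <- if (is.null(g$ln_f_g)) lb$dg else g$ln_f_g + lb$dg
    g$ln_f_b <- if (is.null(g$ln_f_b)) lb$db else g$ln_f_b + lb$db
    dTok[[i]] <- lb$dX
  }
  w <- cfg$window
  for (l in rev(seq_len(cfg$depth))) {
    pre <- paste0("l", l, "_")
    lay <- cache$layouts[[l]]
    for (i in seq_len(n)) {
      cl <- cache$layers[[l]][[i]]
      dX2 <- dTok[[i]]
      g[[paste0(pre, "W2")]] <- acc0(g[[paste0(pre, "W2")]], crossprod(cl$G, dX2))
      g[[paste0(pre, "b2")]] <- acc0(g[[paste0(pre, "b2")]], colSums(dX2))
      dG <- tcrossprod(dX2, params[[paste0(pre, "W2")]])
      dH1 <- dG * gelu_grad(cl$H1)
      g[[paste0(pre, "W1")]] <- acc0(g[[paste0(pre, "W1")]], crossprod(cl$ln2$out, dH1))
      g[[paste0(pre, "b1")]] <- acc0(g[[paste0(pre, "b1")]], colSums(dH1))
      dln2 <- tcrossprod(dH1, params[[paste0(pre, "W1")]])
      lb2 <- ln_backward(dln2, cl$ln2, params[[paste0(pre, "ln2_g")]])
      g[[paste0(pre, "ln2_g")]] <- acc0(g[[paste0(pre, "ln2_g")]], lb2$dg)
      g[[paste0(pre, "ln2_b")]] <- acc0(g[[paste0(pre, "ln2_b")]], lb2$db)
      dX1 <- dX2 + lb2$dX
      dAtt <- dX1
      dln1_out <- matrix(0, T_, E)
      for (wk in seq_along(lay$windows)) {
        wc <- cl$wins[[wk]]
        orig <- wc$orig
        ok <- !is.na(orig)
        dOutw <- matrix(0, w * w, E)
        dOutw[ok, ] <- dAtt[orig[ok], , drop = FALSE]
        mb <- mha_backward(dOutw, wc$cache, params[[paste0(pre, "Wqkv")]],
                           params[[paste0(pre, "Wo")]], want_dbias = TRUE)
        dln1_out[orig[ok], ] <- dln1_out[orig[ok], , drop = FALSE] +
          mb$dX[ok, , drop = FALSE]
        g[[paste0(pre, "Wqkv")]] <- acc0(g[[paste0(pre, "Wqkv")]], mb$dWqkv)
        g[[paste0(pre, "bqkv")]] <- acc0(g[[paste0(pre, "bqkv")]], mb$dbqkv)
        g[[paste0(pre, "Wo")]] <- acc0(g[[paste0(pre, "Wo")]], mb$dWo)
        g[[paste0(pre, "bo")]] <- acc0(g[[paste0(pre, "bo")]], mb$dbo)
        # accumulate rpb gradient through the index table
        drpb <- g[[paste0(pre, "rpb")]]
        if (is.null(drpb)) drpb <- matrix(0, (2 * w - 1)^2, cfg$heads)
        for (h in seq_len(cfg$heads)) {
          db_h <- mb$dbias[[h]]
          drpb[, h] <- drpb[, h] +
            as.vector(tapply(as.vector(db_h), as.vector(cache$rpb_idx), sum)[
              as.character(seq_len((2 * w - 1)^2))]) |>
            (\(v) ifelse(is.na(v), 0, v))()
        }
        g[[paste0(pre, "rpb")]] <- drpb
      }
      lb1 <- ln_backward(dln1_out, cl$ln1, params[[paste0(pre, "ln1_g")]])
      g[[paste0(pre, "ln1_g")]] <- acc0(g[[paste0(pre, "ln1_g")]], lb1$dg)
      g[[paste0(pre, "ln1_b")]] <- acc0(g[[paste0(pre, "ln1_b")]], lb1$db)
      dTok[[i]] <- dX1 + lb1$dX
    }
  }
  # pooling backward into the stem output
  p <- cfg$patch
  d1 <- cache$stack_dim
  dpool_all <- array(0, c(Ht, Wt, E, n))
  for (i in seq_len(n)) dpool_all[, , , i] <- array(dTok[[i]], c(Ht, Wt, E))
  tmp <- array(rep(as.vector(dpool_all) / (p * p), each = p * p),
               c(p, p, Ht, Wt, E, n))
  dStemOut <- array(aperm(tmp, c(1, 3, 2, 4, 5, 6)), c(Ht * p, Wt * p, E, n))
  if (Ht * p < d1[1] || Wt * p < d1[2]) {
    full <- array(0, c(d1[1], d1[2], E, n))
    full[seq_len(Ht * p), seq_len(Wt * p), , ] <- dStemOut
    dStemOut <- full
  }
  gs <- stem_backward(params, cfg, cache$stem, dStemOut)
  for (nm in names(gs)) g[[nm]] <- gs[[nm]]
  g
}

acc0 <- function(a, b) if (is.null(a)) b else a + b

# ---- interest-point saliency ------------------------------------------

#' Greedy True-Score interest-point selection
#'
#' Balances detection confidence and spatial dispersion:
#' `T_i = alpha * s_i + (1 - alpha) * mean_j min(1, d_ij / L)` over the
#' already-selected points (the diversity term is defined as 1 while the
#' selection is empty). Points are picked greedily by descending T,
#' recomputed after every pick; ties break to the lowest candidate index.
#'
#' @param points An `interest_points` data frame (scores in \[0,1\]).
#' @param alpha Confidence/diversity trade-off in \[0,1\] (default 0.7).
#' @param L Distance normalizer (> 0); defaults to a quarter of the image
#'   diagonal implied by the point spread when not given explicitly.
#' @param n_keep Number of points to keep.
#' @return The selected points with a `true_score` column, in selection
#'   order.
#' @export
true_score_select <- function(points, alpha = 0.7, L = NULL, n_keep = 32L) {
  if (!is.null(L) && L <= 0) stop("L must be > 0")
  if (nrow(points) == 0) return(cbind(points, true_score = numeric(0)))
  if (is.null(L)) L <- sqrt((max(points$x) + 1)^2 + (max(points$y) + 1)^2) / 4
  n_keep <- min(n_keep, nrow(points))
  cand <- seq_len(nrow(points))
  sel <- integer(0)
  tsel <- numeric(0)
  while (length(sel) < n_keep) {
    if (length(sel) == 0) {
      div <- rep(1, length(cand))
    } else {
      div <- vapply(cand, function(i) {
        dd <- sqrt((points$x[i] - points$x[sel])^2 +
                   (points$y[i] - points$y[sel])^2)
        mean(pmin(1, dd / L))
      }, numeric(1))
    }
    Tsc <- alpha * points$score[cand] + (1 - alpha) * div
    k <- which.max(Tsc)
    sel <- c(sel, cand[k])
    tsel <- c(tsel, Tsc[k])
    cand <- cand[-k]
    if (length(cand) == 0) break
  }
  out <- points[sel, , drop = FALSE]
  out$true_score <- tsel
  rownames(out) <- NULL
  out
}

#' Project scored points onto the transformer token grid
#'
#' Floor projection with stride p: `tx = floor(x / p)`, `ty = floor(y / p)`
#' (0-based); collisions within a token resolve by taking the maximum
#' true score. Untouched tokens are 0.
#'
#' @param points Points with a `true_score` column (0-based x, y).
#' @param p Patch stride (>= 1).
#' @param grid_dim Token grid size `c(Ht, Wt)`.
#' @return Ht x Wt saliency matrix in \[0,1\].
#' @export
saliency_map <- function(points, p, grid_dim) {
  if (p < 1) stop("stride must be >= 1")
  H <- matrix(0, grid_dim[1], grid_dim[2])
  if (nrow(points) == 0) return(H)
  tx <- pmin(floor(points$x / p), grid_dim[2] - 1)
  ty <- pmin(floor(points$y / p), grid_dim[1] - 1)
  ts <- if (!is.null(points$true_score)) points$true_score else points$score
  for (k in seq_len(nrow(points)))
    H[ty[k] + 1, tx[k] + 1] <- max(H[ty[k] + 1, tx[k] + 1], ts[k])
  H
}

#' Build the four per-modality saliency maps for one sample
#'
#' @param mod_points Named list of per-modality `interest_points` (names
#'   fusion, sobel, moments, gabor).
#' @param stack_dim Spatial size of the stack `c(H, W)`.
#' @param cfg A [texture_config()] (patch stride, True-Score defaults).
#' @param alpha,n_keep True-Score parameters.
#' @return Named list of token-grid saliency matrices.
#' @export
build_saliency <- function(mod_points, stack_dim, cfg = texture_config(),
                           alpha = 0.7, n_keep = 32L) {
  p <- cfg$patch
  gd <- c(stack_dim[1] %/% p, stack_dim[2] %/% p)
  L <- sqrt(stack_dim[1]^2 + stack_dim[2]^2) / 4
  out <- list()
  for (m in c("fusion", "sobel", "moments", "gabor")) {
    pts <- mod_points[[m]]
    if (is.null(pts) || nrow(pts) == 0) { out[[m]] <- matrix(0, gd[1], gd[2]); next }
    sel <- true_score_select(pts, alpha = alpha, L = L, n_keep = n_keep)
    out[[m]] <- saliency_map(sel, p, gd)
  }
  out
}

# ---- training / prediction --------------------------------------------

#' Train the texture branch
#'
#' AdamW + cross-entropy on 12-channel stacks with per-modality saliency
#' guidance. Missing saliency falls back to zero maps with a warning
#' (plain windowed attention).
#'
#' @param stacks List of H x W x 12 arrays.
#' @param saliency List (one entry per sample) of named lists of token-grid
#'   saliency matrices, or NULL.
#' @param labels Integer class labels.
#' @param cfg A [texture_config()].
#' @param epochs,batch_size,lr Training schedule (desk scale; the reference
#'   schedule is 300 epochs, batch 32, lr 3e-4).
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return A `texture_former` object (`params`, `config`, `state` with BN
#'   running statistics, `history`).
#' @export
train_texture <- function(stacks, saliency, labels, cfg = NULL, epochs = 40L,
                          batch_size = 16L, lr = 3e-4, seed = 1L,
                          verbose = FALSE) {
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (is.null(cfg)) cfg <- texture_config(n_classes = max(labels))
  if (is.null(saliency)) {
    warning("no saliency maps supplied: training with zero saliency")
    saliency <- vector("list", length(stacks))
  }
  params <- texture_init(cfg, seed)
  state <- texture_state_init(cfg)
  mask <- lapply(params, function(p) 0)
  for (nm in names(params))
    if (grepl("^W", nm) || grepl("_W(qkv|o|1|2)$", nm)) mask[[nm]] <- 1
  opt <- adamw_init(params)
  n <- length(stacks)
  history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (s in seq(1, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        fw <- texture_forward(params, cfg, stacks[idx], saliency[idx],
                              state, train = TRUE)
        state <- fw$state
        ce <- cross_entropy(fw$logits, labels[idx])
        gr <- texture_backward(params, cfg, fw$cache, ce$dlogits)
        upd <- adamw_step(params, gr, opt, lr, decay_mask = mask)
        params <- upd$params; opt <- upd$state
        losses <- c(losses, ce$loss)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, history[ep]))
    }
  })
  structure(list(params = params, config = cfg, state = state,
                 history = history),
            class = "texture_former")
}

#' @export
print.texture_former <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<texture_former> %d-ch stem -> %d, embed %d, depth %d, heads %d, window %d, %d classes\n",
    cfg$in_ch, cfg$mix, cfg$embed, cfg$depth, cfg$heads, cfg$window,
    cfg$n_classes))
  if (length(x$history)) cat(sprintf("final training loss: %.4f\n", utils::tail(x$history, 1)))
  invisible(x)
}

#' Logits of the texture branch (eval mode)
#'
#' @param model A `texture_former`.
#' @param stacks List of stacks.
#' @param saliency Per-sample saliency lists (or NULL for zero bias).
#' @return n x K logit matrix.
#' @export
texture_logits <- function(model, stacks, saliency = NULL) {
  if (is.null(saliency)) saliency <- vector("list", length(stacks))
  texture_forward(model$params, model$config, stacks, saliency, model$state,
                  train = FALSE)$logits
}

#' Predict species from texture stacks
#'
#' @param object A `texture_former`.
#' @param newdata List of H x W x 12 stacks.
#' @param saliency Optional per-sample saliency lists.
#' @param type `"class"` or `"logits"`.
#' @param ... Unused.
#' @return Class labels or logits.
#' @export
predict.texture_former <- function(object, newdata, saliency = NULL,
                                   type = c("class", "logits"), ...) {
  type <- match.arg(type)
  L <- texture_logits(object, newdata, saliency)
  if (type == "logits") return(L)
  max.col(L, ties.method = "first")
}
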