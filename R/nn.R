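# Minimal neural-network primitives in base R matrix code: GELU, layer
# normalization, row softmax, cross-entropy, and AdamW. Every layer has an
# explicit backward pass; gradients are exercised by finite-difference
# checks in the test suite.

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# per-row layer normalization with affine; eps matches common defaults
ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, `*`)
  m <- ncol(xhat)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# softmax cross-entropy over logits (n x K); labels in 1..K
cross_entropy <- function(logits, labels) {
  n <- nrow(logits)
  P <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dlogits <- P
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n)
}

linear_forward <- function(X, W, b) sweep(X %*% W, 2, b, `+`)

# AdamW optimizer over a flat named list of numeric arrays. `decay_mask`
# gives the per-parameter weight-decay multiplier (0 for biases/norms).
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01, decay_mask = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    if (is.null(gmat)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    wd <- if (is.null(decay_mask)) 1 else decay_mask[[nm]]
    if (is.null(wd)) wd <- 0
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                         weight_decay * wd * params[[nm]])
  }
  list(params = params, state = state)
}

# truncated-normal-ish initializer (plain normal scaled), seeded by caller
init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# multi-head self-attention over one token sequence X (T x d), with optional
# additive logit bias per head (list of T x T matrices or a single matrix
# broadcast over heads). Returns output and a cache for the backward pass.
mha_forward <- function(X, Wqkv, bqkv, Wo, bo, heads, bias = NULL) {
  T_ <- nrow(X); d <- ncol(X); dh <- d %/% heads
  QKV <- linear_forward(X, Wqkv, bqkv)
  Q <- QKV[, 1:d, drop = FALSE]
  K <- QKV[, (d + 1):(2 * d), drop = FALSE]
  V <- QKV[, (2 * d + 1):(3 * d), drop = FALSE]
  O <- matrix(0, T_, d)
  A_list <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    logit <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    if (!is.null(bias)) {
      bh <- if (is.list(bias)) bias[[h]] else bias
      if (!is.null(bh)) logit <- logit + bh
    }
    A <- softmax_rows(logit)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- linear_forward(O, Wo, bo)
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O,
                               A = A_list, heads = heads, dh = dh))
}

# backward: returns dX and parameter grads; dbias (per head list of T x T)
# is returned for callers that train logit-bias tables (e.g. relative
# position bias).
mha_backward <- function(dOut, cache, Wqkv, Wo, want_dbias = FALSE) {
  X <- cache$X; Q <- cache$Q; K <- cache$K; V <- cache$V
  heads <- cache$heads; dh <- cache$dh
  T_ <- nrow(X); d <- ncol(X)
  dWo <- crossprod(cache$O, dOut)
  dbo <- colSums(dOut)
  dO <- tcrossprod(dOut, Wo)
  dQ <- matrix(0, T_, d); dK <- matrix(0, T_, d); dV <- matrix(0, T_, d)
  dbias <- if (want_dbias) vector("list", heads) else NULL
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, V[, cols, drop = FALSE])
    dV[, cols] <- crossprod(A, dOh)
    dlogit <- A * (dA - rowSums(dA * A))
    if (want_dbias) dbias[[h]] <- dlogit
    dQ[, cols] <- dlogit %*% K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dlogit, Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  dQKV <- cbind(dQ, dK, dV)
  dWqkv <- crossprod(X, dQKV)
  dbqkv <- colSums(dQKV)
  dX <- tcrossprod(dQKV, Wqkv)
  list(dX = dX, dWqkv = dWqkv, dbqkv = dbqkv, dWo = dWo, dbo = dbo,
       dbias = dbias)
}

# accumulate gradient lists elementwise
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
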