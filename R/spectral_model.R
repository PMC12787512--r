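# Spectral branch: a transformer encoder over 128 band tokens whose input
# carries a spectral-derivative prior (reflectance, first and second
# difference), projected to a 64-dim embedding with layer normalization.

#' Derivative input channels for a spectrum
#'
#' First difference `D1[i] = X[i+1] - X[i]` with the last entry replicated,
#' and the second difference obtained by applying the same rule to D1; the
#' three channels (reflectance, D1, D2) all keep length B.
#'
#' @param spectrum Numeric reflectance vector (length >= 3).
#' @return B x 3 matrix with columns reflectance, d1, d2.
#' @export
derivative_channels <- function(spectrum) {
  if (!all(is.finite(spectrum))) stop("non-finite spectrum")
  B <- length(spectrum)
  if (B < 3) stop("need at least 3 bands")
  d1 <- c(diff(spectrum), NA); d1[B] <- d1[B - 1]
  d2 <- c(diff(d1), NA); d2[B] <- d2[B - 1]
  cbind(reflectance = spectrum, d1 = d1, d2 = d2)
}

#' Configuration for the spectral branch
#'
#' @param n_bands Number of bands per spectrum (tokens).
#' @param n_classes Number of species.
#' @param d Embedding dimension (64; heads must divide it).
#' @param depth Encoder depth.
#' @param heads Attention heads.
#' @param mlp_ratio Hidden widening of the MLP.
#' @param dropout Dropout rate during training.
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(n_bands = 128L, n_classes = 10L, d = 64L,
                            depth = 4L, heads = 4L, mlp_ratio = 2,
                            dropout = 0.1) {
  if (d %% heads != 0) stop("heads must divide the embedding dimension")
  structure(list(n_bands = as.integer(n_bands), n_classes = as.integer(n_classes),
                 d = as.integer(d), depth = as.integer(depth),
                 heads = as.integer(heads), mlp_ratio = mlp_ratio,
                 dropout = dropout),
            class = "spectral_config")
}

spectral_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    d <- cfg$d
    p <- list(W_in = init_mat(3, d), b_in = numeric(d),
              ln_in_g = rep(1, d), ln_in_b = numeric(d),
              pos = init_mat(cfg$n_bands, d))
    for (l in seq_len(cfg$depth)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, d)
      p[[paste0(pre, "ln1_b")]] <- numeric(d)
      p[[paste0(pre, "Wqkv")]] <- init_mat(d, 3 * d)
      p[[paste0(pre, "bqkv")]] <- numeric(3 * d)
      p[[paste0(pre, "Wo")]] <- init_mat(d, d)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "ln2_g")]] <- rep(1, d)
      p[[paste0(pre, "ln2_b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- init_mat(d, d * cfg$mlp_ratio)
      p[[paste0(pre, "b1")]] <- numeric(d * cfg$mlp_ratio)
      p[[paste0(pre, "W2")]] <- init_mat(d * cfg$mlp_ratio, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
    }
    p$ln_f_g <- rep(1, d); p$ln_f_b <- numeric(d)
    p$W_head <- init_mat(d, cfg$n_classes)
    p$b_head <- numeric(cfg$n_classes)
    p
  })
}

#' Embed spectral-derivative tokens
#'
#' `E = LN(X W + b)`: each band's 3-channel row is projected to d dimensions
#' and layer-normalized per token.
#'
#' @param input B x 3 matrix from [derivative_channels()].
#' @param W 3 x d projection, `b` length-d offset.
#' @param ln_g,ln_b Layer-norm affine parameters (default identity).
#' @return B x d token matrix.
#' @export
embed_tokens <- function(input, W, b, ln_g = rep(1, ncol(W)),
                         ln_b = numeric(ncol(W))) {
  if (ncol(input) != nrow(W)) stop("input/projection shape mismatch")
  ln_forward(linear_forward(input, W, b), ln_g, ln_b)$out
}

# forward over a batch; X is n x B reflectance. Returns logits and (when
# train=TRUE) the caches needed for the backward pass.
spectral_forward <- function(params, cfg, X, train = FALSE) {
  n <- nrow(X); B <- cfg$n_bands; d <- cfg$d
  stopifnot(ncol(X) == B)
  Xsp <- matrix(0, n * B, 3)
  for (i in seq_len(n)) Xsp[((i - 1) * B + 1):(i * B), ] <- derivative_channels(X[i, ])
  E0 <- linear_forward(Xsp, params$W_in, params$b_in)
  ln_in <- ln_forward(E0, params$ln_in_g, params$ln_in_b)
  E <- ln_in$out + params$pos[rep(seq_len(B), n), ]
  caches <- list(Xsp = Xsp, ln_in = ln_in, layers = vector("list", cfg$depth))
  drop_keep <- 1 - if (train) cfg$dropout else 0
  for (l in seq_len(cfg$depth)) {
    pre <- paste0("l", l, "_")
    ln1 <- ln_forward(E, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    att_out <- matrix(0, n * B, d)
    att_caches <- vector("list", n)
    for (i in seq_len(n)) {
      rows <- ((i - 1) * B + 1):(i * B)
      mh <- mha_forward(ln1$out[rows, , drop = FALSE],
                        params[[paste0(pre, "Wqkv")]], params[[paste0(pre, "bqkv")]],
                        params[[paste0(pre, "Wo")]], params[[paste0(pre, "bo")]],
                        cfg$heads)
      att_out[rows, ] <- mh$out
      att_caches[[i]] <- mh$cache
    }
    mask1 <- if (train && cfg$dropout > 0)
      matrix(stats::rbinom(n * B * d, 1, drop_keep) / drop_keep, n * B, d) else NULL
    if (!is.null(mask1)) att_out <- att_out * mask1
    E1 <- E + att_out
    ln2 <- ln_forward(E1, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    H1 <- linear_forward(ln2$out, params[[paste0(pre, "W1")]], params[[paste0(pre, "b1")]])
    G <- gelu(H1)
    M <- linear_forward(G, params[[paste0(pre, "W2")]], params[[paste0(pre, "b2")]])
    mask2 <- if (train && cfg$dropout > 0)
      matrix(stats::rbinom(n * B * d, 1, drop_keep) / drop_keep, n * B, d) else NULL
    if (!is.null(mask2)) M <- M * mask2
    E2 <- E1 + M
    caches$layers[[l]] <- list(ln1 = ln1, att = att_caches, mask1 = mask1,
                               ln2 = ln2, H1 = H1, G = G, mask2 = mask2)
    E <- E2
  }
  lnf <- ln_forward(E, params$ln_f_g, params$ln_f_b)
  Fh <- lnf$out
  P <- matrix(0, n, d)
  for (i in seq_len(n)) P[i, ] <- colMeans(Fh[((i - 1) * B + 1):(i * B), , drop = FALSE])
  logits <- linear_forward(P, params$W_head, params$b_head)
  caches$lnf <- lnf; caches$P <- P
  list(logits = logits, cache = if (train) caches else NULL)
}

spectral_backward <- function(params, cfg, cache, dlogits) {
  n <- nrow(dlogits); B <- cfg$n_bands; d <- cfg$d
  g <- list()
  g$W_head <- crossprod(cache$P, dlogits)
  g$b_head <- colSums(dlogits)
  dP <- tcrossprod(dlogits, params$W_head)
  dF <- matrix(0, n * B, d)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * B + 1):(i * B)
    dF[rows, ] <- matrix(dP[i, ] / B, B, d, byrow = TRUE)
  }
  lb <- ln_backward(dF, cache$lnf, params$ln_f_g)
  g$ln_f_g <- lb$dg; g$ln_f_b <- lb$db
  dE <- lb$dX
  for (l in rev(seq_len(cfg$depth))) {
    pre <- paste0("l", l, "_")
    cl <- cache$layers[[l]]
    dM <- if (!is.null(cl$mask2)) dE * cl$mask2 else dE
    g[[paste0(pre, "W2")]] <- crossprod(cl$G, dM)
    g[[paste0(pre, "b2")]] <- colSums(dM)
    dG <- tcrossprod(dM, params[[paste0(pre, "W2")]])
    dH1 <- dG * gelu_grad(cl$H1)
    g[[paste0(pre, "W1")]] <- crossprod(cl$ln2$out, dH1)
    g[[paste0(pre, "b1")]] <- colSums(dH1)
    dln2 <- tcrossprod(dH1, params[[paste0(pre, "W1")]])
    lb2 <- ln_backward(dln2, cl$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb2$dg; g[[paste0(pre, "ln2_b")]] <- lb2$db
    dE1 <- dE + lb2$dX
    dAtt <- if (!is.null(cl$mask1)) dE1 * cl$mask1 else dE1
    dln1_out <- matrix(0, n * B, d)
    for (i in seq_len(n)) {
      rows <- ((i - 1) * B + 1):(i * B)
      mb <- mha_backward(dAtt[rows, , drop = FALSE], cl$att[[i]],
                         params[[paste0(pre, "Wqkv")]], params[[paste0(pre, "Wo")]])
      dln1_out[rows, ] <- mb$dX
      g[[paste0(pre, "Wqkv")]] <- if (is.null(g[[paste0(pre, "Wqkv")]])) mb$dWqkv else g[[paste0(pre, "Wqkv")]] + mb$dWqkv
      g[[paste0(pre, "bqkv")]] <- if (is.null(g[[paste0(pre, "bqkv")]])) mb$dbqkv else g[[paste0(pre, "bqkv")]] + mb$dbqkv
      g[[paste0(pre, "Wo")]] <- if (is.null(g[[paste0(pre, "Wo")]])) mb$dWo else g[[paste0(pre, "Wo")]] + mb$dWo
      g[[paste0(pre, "bo")]] <- if (is.null(g[[paste0(pre, "bo")]])) mb$dbo else g[[paste0(pre, "bo")]] + mb$dbo
    }
    lb1 <- ln_backward(dln1_out, cl$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb1$dg; g[[paste0(pre, "ln1_b")]] <- lb1$db
    dE <- dE1 + lb1$dX
  }
  # position embedding: summed over samples
  dpos <- matrix(0, B, d)
  for (i in seq_len(n)) dpos <- dpos + dE[((i - 1) * B + 1):(i * B), , drop = FALSE]
  g$pos <- dpos
  lbi <- ln_backward(dE, cache$ln_in, params$ln_in_g)
  g$ln_in_g <- lbi$dg; g$ln_in_b <- lbi$db
  g$W_in <- crossprod(cache$Xsp, lbi$dX)
  g$b_in <- colSums(lbi$dX)
  g
}

#' Train the spectral branch
#'
#' AdamW + cross-entropy on point spectra with sample labels. All
#' randomness (initialization, batch order, dropout) derives from `seed`, so
#' a fixed seed reproduces the trajectory exactly.
#'
#' @param X n x B matrix of reflectance spectra.
#' @param labels Integer class labels in 1..n_classes.
#' @param cfg A [spectral_config()].
#' @param epochs,batch_size,lr Training schedule (desk-scale defaults; the
#'   reference schedule of 300 epochs, batch 256, lr 1e-4 is available by
#'   configuration).
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return A `spectral_former` object with elements `params`, `config`,
#'   `history` (per-epoch mean loss).
#' @export
train_spectral <- function(X, labels, cfg = NULL, epochs = 40L, batch_size = 64L,
                           lr = 1e-4, seed = 1L, verbose = FALSE) {
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (is.null(cfg)) cfg <- spectral_config(n_bands = ncol(X),
                                           n_classes = max(labels))
  params <- spectral_init(cfg, seed)
  mask <- lapply(params, function(p) 0)
  for (nm in names(params))
    if (grepl("^(W_|l[0-9]+_W)", nm) || nm %in% c("W_head")) mask[[nm]] <- 1
  state <- adamw_init(params)
  n <- nrow(X)
  history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (s in seq(1, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        fw <- spectral_forward(params, cfg, X[idx, , drop = FALSE], train = TRUE)
        ce <- cross_entropy(fw$logits, labels[idx])
        gr <- spectral_backward(params, cfg, fw$cache, ce$dlogits)
        upd <- adamw_step(params, gr, state, lr, decay_mask = mask)
        params <- upd$params; state <- upd$state
        losses <- c(losses, ce$loss)
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d  loss %.4f", ep, history[ep]))
    }
  })
  structure(list(params = params, config = cfg, history = history),
            class = "spectral_former")
}

#' @export
print.spectral_former <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<spectral_former> %d bands, d=%d, depth=%d, heads=%d, %d classes\n",
              cfg$n_bands, cfg$d, cfg$depth, cfg$heads, cfg$n_classes))
  if (length(x$history)) cat(sprintf("final training loss: %.4f\n", utils::tail(x$history, 1)))
  invisible(x)
}

#' Logits of the spectral branch (eval mode)
#'
#' @param model A `spectral_former`.
#' @param X n x B matrix of spectra.
#' @return n x K logit matrix.
#' @export
spectral_logits <- function(model, X) {
  spectral_forward(model$params, model$config, X, train = FALSE)$logits
}

#' Predict species from point spectra
#'
#' For a list of signature matrices (one per sample, rows = interest-point
#' spectra) the sample-level logit is the mean of the per-point logits.
#'
#' @param object A `spectral_former`.
#' @param newdata Matrix of spectra, or list of signature matrices.
#' @param type `"class"` or `"logits"`.
#' @param ... Unused.
#' @return Class labels or logits.
#' @export
predict.spectral_former <- function(object, newdata, type = c("class", "logits"),
                                    ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.data.frame(newdata)) {
    L <- t(vapply(newdata, function(S)
      colMeans(spectral_logits(object, S)), numeric(object$config$n_classes)))
  } else {
    L <- spectral_logits(object, newdata)
  }
  if (type == "logits") return(L)
  max.col(L, ties.method = "first")
}
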