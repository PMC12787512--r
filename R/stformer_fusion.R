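# Per-class learnable late fusion of the spectral and texture branches.
# Both branches stay frozen; only one scalar per class is trained, whose
# sigmoid blends the two logits.

#' Fuse branch logits with per-class weights
#'
#' `fused_k = (1 - sigmoid(lambda_k)) * Ts_k + sigmoid(lambda_k) * Tt_k`:
#' a per-class convex combination with the sigmoid weight on the texture
#' logit. With lambda = 0 the fusion is the exact mean of the branches.
#'
#' @param Ts,Tt n x K logit matrices from the spectral and texture branches.
#' @param lambda Length-K real fusion parameters.
#' @return n x K fused logit matrix.
#' @export
fuse_logits <- function(Ts, Tt, lambda) {
  if (!all(dim(Ts) == dim(Tt))) stop("branch logit shapes differ")
  if (length(lambda) != ncol(Ts)) stop("lambda length must equal class count")
  w <- sigmoid(lambda)
  sweep(Ts, 2, 1 - w, `*`) + sweep(Tt, 2, w, `*`)
}

#' Regularized fusion loss
#'
#' Softmax cross-entropy of the fused logits plus
#' `beta * mean((sigmoid(lambda) - 0.5)^2)`, which discourages collapse of
#' the fusion weights to 0 or 1 and vanishes exactly at the neutral point
#' 0.5.
#'
#' @param fused n x K fused logits.
#' @param labels Integer labels in 1..K.
#' @param lambda Length-K fusion parameters.
#' @param beta Regularization strength (default 5e-3; sensible range
#'   1e-4..1e-2).
#' @return List with `loss`, `ce`, `reg` and `dfused`/`dlambda_reg`
#'   gradients.
#' @export
fusion_loss <- function(fused, labels, lambda, beta = 5e-3) {
  if (nrow(fused) == 0) stop("empty batch")
  ce <- cross_entropy(fused, labels)
  s <- sigmoid(lambda)
  reg <- mean((s - 0.5)^2)
  dlambda_reg <- beta * 2 * (s - 0.5) * s * (1 - s) / length(lambda)
  list(loss = ce$loss + beta * reg, ce = ce$loss, reg = reg,
       dfused = ce$dlogits, dlambda_reg = dlambda_reg)
}

#' Train the per-class fusion weights
#'
#' Given fixed branch logits, optimizes only the K fusion scalars (AdamW,
#' full batch) from the neutral initialization lambda = 0. The per-epoch
#' sigmoid(lambda) trajectory is recorded.
#'
#' @param Ts,Tt n x K branch logits of the training samples.
#' @param labels Integer labels.
#' @param beta Regularization strength.
#' @param epochs,lr Optimization schedule.
#' @return List with `lambda`, `weights` (sigmoid(lambda)), `trajectory`
#'   (epochs x K matrix of sigmoid(lambda)), `history` (loss per epoch).
#' @export
train_fusion_weights <- function(Ts, Tt, labels, beta = 5e-3, epochs = 100L,
                                 lr = 1e-2) {
  K <- ncol(Ts)
  lambda <- numeric(K)
  st <- adamw_init(list(lambda = lambda))
  traj <- matrix(0, epochs, K)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fused <- fuse_logits(Ts, Tt, lambda)
    fl <- fusion_loss(fused, labels, lambda, beta)
    s <- sigmoid(lambda)
    # dCE/dlambda_k = sum_i dfused_ik * (Tt_ik - Ts_ik) * s'(lambda_k)
    dl <- colSums(fl$dfused * (Tt - Ts)) * s * (1 - s) + fl$dlambda_reg
    upd <- adamw_step(list(lambda = lambda), list(lambda = dl), st, lr,
                      weight_decay = 0)
    lambda <- upd$params$lambda
    st <- upd$state
    traj[ep, ] <- sigmoid(lambda)
    history[ep] <- fl$loss
  }
  list(lambda = lambda, weights = sigmoid(lambda), trajectory = traj,
       history = history)
}

#' Complementary collaborative fusion of two trained branches
#'
#' Computes frozen-branch logits for the training samples and learns only
#' the per-class fusion weights. Branch parameters are not touched.
#'
#' @param spectral A trained `spectral_former`.
#' @param texture A trained `texture_former`.
#' @param signatures List of per-sample signature matrices (interest-point
#'   spectra).
#' @param stacks List of per-sample texture stacks.
#' @param saliency Per-sample saliency lists (or NULL).
#' @param labels Integer labels.
#' @param beta,epochs,lr See [train_fusion_weights()].
#' @return An `st_former` object with both branches, `lambda`, `weights`
#'   and the sigmoid trajectory.
#' @export
st_former <- function(spectral, texture, signatures, stacks, saliency, labels,
                      beta = 5e-3, epochs = 100L, lr = 1e-2) {
  if (spectral$config$n_classes != texture$config$n_classes)
    stop("branch class counts differ")
  Ts <- predict(spectral, signatures, type = "logits")
  Tt <- predict(texture, stacks, saliency = saliency, type = "logits")
  fw <- train_fusion_weights(Ts, Tt, labels, beta, epochs, lr)
  structure(list(spectral = spectral, texture = texture, lambda = fw$lambda,
                 weights = fw$weights, trajectory = fw$trajectory,
                 history = fw$history),
            class = "st_former")
}

#' @export
print.st_former <- function(x, ...) {
  cat("<st_former> per-class texture weights sigmoid(lambda):\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Plot the fusion-weight trajectories
#'
#' One curve of sigmoid(lambda_k) per class against training epoch.
#'
#' @param x An `st_former` (or the result of [train_fusion_weights()]).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.st_former <- function(x, ...) {
  graphics::matplot(x$trajectory, type = "l", lty = 1,
                    xlab = "epoch", ylab = expression(sigma(lambda[k])),
                    ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Predict with the fused model
#'
#' @param object An `st_former`.
#' @param signatures,stacks,saliency Per-sample inputs as in [st_former()].
#' @param type `"class"` or `"logits"`.
#' @param ... Unused.
#' @return Class labels or fused logits.
#' @export
predict.st_former <- function(object, signatures, stacks, saliency = NULL,
                              type = c("class", "logits"), ...) {
  type <- match.arg(type)
  Ts <- predict(object$spectral, signatures, type = "logits")
  Tt <- predict(object$texture, stacks, saliency = saliency, type = "logits")
  L <- fuse_logits(Ts, Tt, object$lambda)
  if (type == "logits") return(L)
  max.col(L, ties.method = "first")
}

#' Row-normalized confusion matrix
#'
#' @param truth,pred Integer class vectors.
#' @param K Number of classes (default: max observed).
#' @return K x K matrix whose rows sum to 1 (true class in rows).
#' @export
confusion_matrix <- function(truth, pred, K = max(c(truth, pred))) {
  M <- matrix(0, K, K)
  for (i in seq_along(truth)) M[truth[i], pred[i]] <- M[truth[i], pred[i]] + 1
  rs <- rowSums(M)
  sweep(M, 1, pmax(rs, 1), `/`)
}
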