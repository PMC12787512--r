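# Texture feature space built on the PCA first-principal-component image:
# Sobel edges (2 channels), second-order geometric moments (3), Gabor energy
# (6), stacked with the fused band image into a 12-channel tensor.

#' First principal component image of a cube
#'
#' Pixels are observations, bands are variables; the first component score
#' map is sign-aligned to correlate positively with the mean band image and
#' min-max normalized to \[0,1\]. The `"randomized"` solver uses a seeded
#' Gaussian sketch with power iterations (useful at large band counts); the
#' `"exact"` solver diagonalizes the B x B covariance.
#'
#' @param cube A [hyper_cube()].
#' @param solver `"exact"` or `"randomized"`.
#' @param rank Sketch size for the randomized solver.
#' @param seed Seed for the randomized sketch.
#' @return H x W matrix in \[0,1\] (class `"pca_image"`).
#' @export
pca_first_component <- function(cube, solver = c("exact", "randomized"),
                                rank = 8L, seed = 1L) {
  solver <- match.arg(solver)
  d <- dim(cube$values)
  X <- matrix(cube$values, d[1] * d[2], d[3])
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (max(abs(Xc)) < 1e-14) {
    warning("zero-variance cube: PCA image is all zero")
    return(structure(matrix(0, d[1], d[2]), class = c("pca_image", "matrix", "array")))
  }
  if (solver == "exact") {
    C <- crossprod(Xc)
    v1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
  } else {
    v1 <- with_seed(seed, {
      Om <- matrix(stats::rnorm(d[3] * rank), d[3], rank)
      Y <- Xc %*% Om
      for (q in 1:2) {
        Y <- qr.Q(qr(Y))
        Y <- Xc %*% crossprod(Xc, Y)
      }
      Q <- qr.Q(qr(Y))
      Bs <- crossprod(Q, Xc)            # rank x B
      sv <- svd(Bs)
      sv$v[, 1]
    })
  }
  scores <- as.vector(Xc %*% v1)
  if (sum(scores * rowMeans(X)) < 0) scores <- -scores
  img <- matrix(scores, d[1], d[2])
  structure(norm01(img), class = c("pca_image", "matrix", "array"))
}

#' Sobel edge features (2 channels)
#'
#' Horizontal and vertical 3x3 Sobel gradients; each absolute gradient map
#' is min-max normalized and the two are stacked as `[N(|Gx|), N(|Gy|)]`.
#'
#' @param I 2-D image matrix (e.g. a [pca_first_component()]).
#' @return H x W x 2 array in \[0,1\].
#' @export
sobel_features <- function(I) {
  I <- unclass(I)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # responds to x (column) changes
  sy <- t(sx)
  gx <- abs(ebi_filter(I, sx))
  gy <- abs(ebi_filter(I, sy))
  out <- array(0, c(nrow(I), ncol(I), 2))
  out[, , 1] <- norm01(gx); out[, , 2] <- norm01(gy)
  out
}

moment_kernels <- function(w = 7L) {
  if (w %% 2L != 1L || w < 3L) stop("moment window must be odd and >= 3")
  r <- (w - 1L) %/% 2L
  xs <- matrix(rep(-r:r, each = w), w, w)   # column offsets
  ys <- t(xs)                               # row offsets
  list(k20 = xs^2, k02 = ys^2, k11 = xs * ys)
}

#' Second-order geometric moment features (3 channels)
#'
#' Convolution of the image with polynomial weight kernels x^2, y^2, xy over
#' a centred w x w window (x = column offset); channels `[M20, M02, M11]`,
#' each min-max normalized. On a unit image the raw interior M20/M02 value
#' is `w * sum(x^2) = 196` for w = 7.
#'
#' @param I 2-D image matrix.
#' @param w Window size (odd, default 7).
#' @param normalize Min-max normalize the channels (default TRUE; FALSE
#'   returns raw moment responses).
#' @return H x W x 3 array.
#' @export
moment_features <- function(I, w = 7L, normalize = TRUE) {
  I <- unclass(I)
  k <- moment_kernels(w)
  m20 <- ebi_filter(I, k$k20)
  m02 <- ebi_filter(I, k$k02)
  m11 <- ebi_filter(I, k$k11)
  out <- array(0, c(nrow(I), ncol(I), 3))
  if (normalize) {
    out[, , 1] <- norm01(m20); out[, , 2] <- norm01(m02); out[, , 3] <- norm01(m11)
  } else {
    out[, , 1] <- m20; out[, , 2] <- m02; out[, , 3] <- m11
  }
  out
}

gabor_kernel <- function(theta_deg, lambda = 8, sigma = 0.56 * 8, gamma = 0.5,
                         max_radius = Inf) {
  r <- min(ceiling(4 * sigma), max_radius)
  xs <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1, 2 * r + 1)  # column offsets
  ys <- t(xs)
  th <- theta_deg * pi / 180
  xp <- xs * cos(th) + ys * sin(th)
  yp <- -xs * sin(th) + ys * cos(th)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) * cos(2 * pi * xp / lambda)
}

#' Gabor energy features (6 channels)
#'
#' Oriented Gabor filters at 0, 30, 60, 90, 120, 150 degrees with wavelength
#' lambda = 8 px, sigma = 0.56 lambda, aspect gamma = 0.5, truncated at 4
#' sigma. The absolute filter response (energy) per orientation is min-max
#' normalized; channels follow the orientation order.
#'
#' @param I 2-D image matrix.
#' @param orientations Orientations in degrees.
#' @param lambda,sigma,gamma Gabor parameters.
#' @param normalize Min-max normalize each channel (default); FALSE returns
#'   raw energies (useful for comparing orientations on an absolute scale).
#' @return H x W x 6 array (in \[0,1\] when normalized).
#' @export
gabor_features <- function(I, orientations = c(0, 30, 60, 90, 120, 150),
                           lambda = 8, sigma = 0.56 * lambda, gamma = 0.5,
                           normalize = TRUE) {
  I <- unclass(I)
  rmax <- (min(dim(I)) - 1) %/% 2    # kernel must fit inside the image
  out <- array(0, c(nrow(I), ncol(I), length(orientations)))
  for (k in seq_along(orientations)) {
    g <- gabor_kernel(orientations[k], lambda, sigma, gamma, max_radius = rmax)
    e <- abs(ebi_filter(I, g))
    out[, , k] <- if (normalize) norm01(e) else e
  }
  out
}

#' Top-K salient points of one texture modality
#'
#' The per-modality score matrix is the gradient magnitude for Sobel
#' (sqrt(Gx^2 + Gy^2)), the L2 norm across channels for moments, the maximum
#' energy response for Gabor, and the (normalized) map itself for the fusion
#' channel; points are then extracted exactly like spectral interest points
#' (local maxima, relative threshold, spacing, top K).
#'
#' @param feat Feature array (H x W x C) or matrix for the fusion modality.
#' @param modality One of `"fusion"`, `"sobel"`, `"moments"`, `"gabor"`.
#' @param K,t,d See [extract_points()].
#' @return An `interest_points` data frame.
#' @export
modality_points <- function(feat, modality = c("fusion", "sobel", "moments",
                                               "gabor"),
                            K = 100L, t = 0.02, d = 6) {
  modality <- match.arg(modality)
  score <- switch(modality,
    fusion = norm01(unclass(feat)),
    sobel = sqrt(feat[, , 1]^2 + feat[, , 2]^2),
    moments = sqrt(feat[, , 1]^2 + feat[, , 2]^2 + feat[, , 3]^2),
    gabor = apply(feat, c(1, 2), max))
  if (max(score) <= 0) {
    warning(sprintf("constant %s map: no salient points", modality))
    return(structure(data.frame(x = integer(0), y = integer(0),
                                score = numeric(0)),
                     class = c("interest_points", "data.frame")))
  }
  extract_points(norm01(score), t = t, d = d, K = K)
}

#' Build the 12-channel texture stack
#'
#' Channel order is fixed: fused image (1), Sobel (2), moments (3), Gabor
#' (6). All channels are min-max normalized to \[0,1\] and spatially
#' aligned.
#'
#' @param fused Fused band image (matrix).
#' @param sobel,moments,gabor Feature arrays from the corresponding
#'   extractors.
#' @return H x W x 12 array (class `"texture_stack"`).
#' @export
build_texture_stack <- function(fused, sobel, moments, gabor) {
  h <- nrow(fused); w <- ncol(fused)
  ok <- function(a, nc) length(dim(a)) == 3 && all(dim(a) == c(h, w, nc))
  if (!ok(sobel, 2) || !ok(moments, 3) || !ok(gabor, 6))
    stop("feature shapes do not match the fused image")
  out <- array(0, c(h, w, 12))
  out[, , 1] <- norm01(unclass(fused))
  out[, , 2:3] <- sobel
  out[, , 4:6] <- moments
  out[, , 7:12] <- gabor
  structure(out, class = c("texture_stack", "array"))
}

#' Full texture-space construction for one cube
#'
#' @param cube A [hyper_cube()].
#' @param fused Fused band image for the fusion channel.
#' @param K Salient points per modality.
#' @return List with `stack` (H x W x 12), `pca` (the base image) and
#'   `points` (named list of per-modality `interest_points`).
#' @export
texture_space <- function(cube, fused, K = 100L) {
  pca <- pca_first_component(cube)
  sob <- sobel_features(pca)
  mom <- moment_features(pca)
  gab <- gabor_features(pca)
  stack <- build_texture_stack(fused, sob, mom, gab)
  pts <- list(
    fusion = modality_points(stack[, , 1], "fusion", K),
    sobel = modality_points(sob, "sobel", K),
    moments = modality_points(mom, "moments", K),
    gabor = modality_points(gab, "gabor", K))
  list(stack = stack, pca = pca, points = pts)
}
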