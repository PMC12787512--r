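# Interest-point extraction from fused band images: frequency-domain
# degridding, local enhancement, a six-feature saliency score map, and
# spatially-spread top-K peak picking. Point coordinates are 0-based with
# x = column, y = row, origin at the top-left pixel.

norm01 <- function(m) {
  lo <- min(m); hi <- max(m)
  # treat numerically-constant maps (FFT filtering residue) as constant
  if (hi - lo <= 1e-12 * max(1, abs(hi))) return(m * 0)
  (m - lo) / (hi - lo)
}

ebi_filter <- function(img, kernel) {
  EBImage::imageData(EBImage::filter2(EBImage::Image(img), kernel,
                                      boundary = "replicate"))
}

# local box mean via cumulative sums (truncated windows at the borders are
# normalized by their actual size)
box_filter <- function(img, w) {
  r <- w %/% 2L
  n1 <- nrow(img); n2 <- ncol(img)
  win_sum_rows <- function(M) {
    S <- rbind(0, apply(M, 2, cumsum))
    hi <- pmin(seq_len(nrow(M)) + r, nrow(M)) + 1L
    lo <- pmax(seq_len(nrow(M)) - r - 1L, 0L) + 1L
    S[hi, , drop = FALSE] - S[lo, , drop = FALSE]
  }
  cnt1 <- pmin(seq_len(n1) + r, n1) - pmax(seq_len(n1) - r - 1L, 0L)
  cnt2 <- pmin(seq_len(n2) + r, n2) - pmax(seq_len(n2) - r - 1L, 0L)
  out <- t(win_sum_rows(t(win_sum_rows(img))))
  out / (cnt1 %o% cnt2)
}

gauss_blur <- function(img, sigma) {
  r <- 2 * ceiling(3 * sigma) + 1
  rmax <- min(dim(img)) - 1
  if (rmax %% 2 == 0) rmax <- rmax - 1
  EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma,
                                    radius = min(r, rmax)))
}

#' Frequency-domain notch degridding
#'
#' Detects isolated peaks in the FFT magnitude spectrum (periodic
#' interference) and suppresses them with a Gaussian notch mask
#' `prod(1 - alpha * exp(-d^2 / (2 sigma^2)))` over the detected centres and
#' their conjugates. Peaks must clear both a global magnitude percentile and
#' a prominence factor over their local median, and must lie outside a
#' low-frequency exclusion disc that protects macro-texture (rings) and the
#' DC term; with no detected peaks the operator is the identity.
#'
#' @param img 2-D numeric image.
#' @param alpha Suppression intensity in \[0,1\] (default 0.85).
#' @param sigma Notch radius in frequency-plane pixels (default 3.5).
#' @param percentile Magnitude percentile a peak must exceed (default 99.5).
#' @param dc_exclude Low-frequency exclusion radius as a fraction of the
#'   smaller image side (default 0.12).
#' @param prominence Required ratio of peak magnitude to its 7x7
#'   neighbourhood median (default 6).
#' @return The filtered image (real part), same shape; detected peak centres
#'   attached as attribute `"peaks"` (matrix of frequency offsets).
#' @export
notch_degrid <- function(img, alpha = 0.85, sigma = 3.5, percentile = 99.5,
                         dc_exclude = 0.12, prominence = 6) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  h <- nrow(img); w <- ncol(img)
  F <- stats::fft(img)
  # peak DETECTION runs on a Hann-windowed spectrum: windowing suppresses
  # the leakage sidelobes of non-integer-frequency image content (rings)
  # that would otherwise mimic isolated interference peaks; the notch mask
  # itself is applied to the unwindowed transform
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  mag <- Mod(stats::fft(img * (hann(h) %o% hann(w))))
  # frequency offsets from DC with wrap-around
  fu <- ifelse(0:(h - 1) > h / 2, 0:(h - 1) - h, 0:(h - 1))
  fv <- ifelse(0:(w - 1) > w / 2, 0:(w - 1) - w, 0:(w - 1))
  dist_dc <- sqrt(outer(fu^2, fv^2, "+"))
  excl <- dc_exclude * min(h, w)
  # local maxima of the magnitude (8-neighbourhood on the torus)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  is_max <- matrix(TRUE, h, w)
  for (s in seq_len(nrow(shifts))) {
    if (shifts$dr[s] == 0 && shifts$dc[s] == 0) next
    nb <- mag[(((0:(h - 1)) + shifts$dr[s]) %% h) + 1,
              (((0:(w - 1)) + shifts$dc[s]) %% w) + 1]
    is_max <- is_max & (mag >= nb)
  }
  # local median via 7x7 neighbourhood (torus), computed only at candidates
  cand <- which(is_max & dist_dc > excl &
                mag > stats::quantile(mag[dist_dc > excl], percentile / 100))
  keep <- integer(0)
  for (ci in cand) {
    r <- (ci - 1) %% h + 1; cc <- (ci - 1) %/% h + 1
    rows <- (((r - 3):(r + 3)) - 1) %% h + 1
    cols <- (((cc - 3):(cc + 3)) - 1) %% w + 1
    nbhd <- mag[rows, cols]
    if (mag[r, cc] > prominence * stats::median(nbhd)) keep <- c(keep, ci)
  }
  if (length(keep) == 0L) {
    attr(img, "peaks") <- matrix(numeric(0), 0, 2)
    return(img)
  }
  pu <- fu[(keep - 1) %% h + 1]
  pv <- fv[(keep - 1) %/% h + 1]
  # conjugate peaks are included automatically when both local maxima are
  # detected, but enforce symmetry explicitly
  centres <- unique(rbind(cbind(pu, pv), cbind(-pu, -pv)))
  mask <- matrix(1, h, w)
  for (i in seq_len(nrow(centres))) {
    du <- pmin(abs(fu - centres[i, 1]), h - abs(fu - centres[i, 1]))
    dv <- pmin(abs(fv - centres[i, 2]), w - abs(fv - centres[i, 2]))
    d2 <- outer(du^2, dv^2, "+")
    mask <- mask * (1 - alpha * exp(-d2 / (2 * sigma^2)))
  }
  out <- Re(stats::fft(F * mask, inverse = TRUE)) / (h * w)
  attr(out, "peaks") <- centres
  out
}

#' Non-local means denoising
#'
#' Shifted-patch formulation: for every offset in the search window the
#' patchwise squared difference is box-filtered and converted to a weight
#' `exp(-ssd / h^2)`; the output is the weight-normalized average. `strength`
#' follows the 8-bit convention (h = strength / 255 on \[0,1\] images).
#'
#' @param img 2-D numeric image in \[0,1\].
#' @param strength Filter strength on the 0-255 scale (default 4).
#' @param search Search window side (odd, default 7).
#' @param patch Patch side (odd, default 5).
#' @return The denoised image.
#' @export
nl_means <- function(img, strength = 4, search = 7L, patch = 5L) {
  h <- strength / 255
  rad <- search %/% 2L
  H <- nrow(img); W <- ncol(img)
  pad <- rad
  P <- matrix(0, H + 2 * pad, W + 2 * pad)
  P[(pad + 1):(pad + H), (pad + 1):(pad + W)] <- img
  # replicate-pad edges
  P[1:pad, ] <- P[rep(pad + 1, pad), ]; P[(pad + H + 1):(pad + H + pad), ] <- P[rep(pad + H, pad), ]
  P[, 1:pad] <- P[, rep(pad + 1, pad)]; P[, (pad + W + 1):(pad + W + pad)] <- P[, rep(pad + W, pad)]
  acc <- img * 0; wsum <- img * 0
  for (dr in -rad:rad) {
    for (dc in -rad:rad) {
      sh <- P[(pad + 1 + dr):(pad + H + dr), (pad + 1 + dc):(pad + W + dc)]
      if (dr == 0 && dc == 0) { wgt <- matrix(1, H, W) }
      else {
        ssd <- box_filter((img - sh)^2, patch)
        wgt <- exp(-ssd / (h * h))
      }
      acc <- acc + wgt * sh
      wsum <- wsum + wgt
    }
  }
  acc / wsum
}

#' Local enhancement chain for fused images
#'
#' NL-means denoising, CLAHE (8x8 tiles, clip limit 2), unsharp masking
#' (radius 1.2, amount 1.3) and gamma correction (0.95), in that order,
#' clipped to \[0,1\]. The homomorphic mode replaces CLAHE + unsharp with a
#' log-domain decomposition that amplifies the high-frequency reflectance
#' term (for unevenly illuminated samples). Constant images pass through
#' unchanged.
#'
#' @param img 2-D numeric image in \[0,1\].
#' @param nlm_strength NL-means strength (8-bit scale).
#' @param clahe_grid CLAHE tile grid (default 8).
#' @param clahe_clip CLAHE clip limit (default 2).
#' @param unsharp_radius,unsharp_amount Unsharp-mask Gaussian radius and gain.
#' @param gamma Gamma exponent (default 0.95).
#' @param homomorphic Use the homomorphic variant instead of CLAHE + unsharp.
#' @param homo_cutoff,homo_gain Homomorphic low-pass sigma and reflectance
#'   gain.
#' @return The enhanced image in \[0,1\].
#' @export
enhance <- function(img, nlm_strength = 4, clahe_grid = 8L, clahe_clip = 2,
                    unsharp_radius = 1.2, unsharp_amount = 1.3, gamma = 0.95,
                    homomorphic = FALSE, homo_cutoff = 12, homo_gain = 1.6) {
  stopifnot(all(img >= 0), all(img <= 1))
  if (max(img) - min(img) < 1e-12) return(img)  # degenerate: nothing to enhance
  out <- nl_means(img, nlm_strength)
  if (homomorphic) {
    lg <- log1p(out)
    low <- gauss_blur(lg, homo_cutoff)
    out <- expm1(low + homo_gain * (lg - low))
    out <- norm01(out)
  } else {
    out <- EBImage::imageData(EBImage::clahe(EBImage::Image(out),
                                             nx = clahe_grid, ny = clahe_grid,
                                             limit = clahe_clip))
    blur <- gauss_blur(out, unsharp_radius)
    out <- out + unsharp_amount * (out - blur)
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out <- out^gamma
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

# six raw saliency feature maps
saliency_features <- function(img, harris_k = 0.04, harris_sigma = 1,
                              entropy_window = 9L, entropy_bins = 32L,
                              snr_window = 9L, snr_cap = 10,
                              dog_sigmas = c(1, 2)) {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dx (columns)
  sy <- t(sx)
  Ix <- ebi_filter(img, sx); Iy <- ebi_filter(img, sy)
  A <- gauss_blur(Ix * Ix, harris_sigma)
  B <- gauss_blur(Iy * Iy, harris_sigma)
  C <- gauss_blur(Ix * Iy, harris_sigma)
  harris <- (A * B - C * C) - harris_k * (A + B)^2
  q <- floor(pmin(pmax(img, 0), 1 - 1e-12) * entropy_bins)
  ent <- img * 0
  for (b in 0:(entropy_bins - 1L)) {
    p <- pmax(box_filter((q == b) * 1, entropy_window), 0)
    ent <- ent - p * log2(p + (p <= 0))   # p log p, defined as 0 at p = 0
  }
  sobel <- sqrt(Ix^2 + Iy^2)
  lap <- abs(ebi_filter(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)))
  dog <- abs(gauss_blur(img, dog_sigmas[1]) - gauss_blur(img, dog_sigmas[2]))
  mu <- box_filter(img, snr_window)
  sd2 <- pmax(box_filter(img^2, snr_window) - mu^2, 0)
  snr <- pmin(mu / (sqrt(sd2) + 1e-6), snr_cap)
  list(harris = harris, entropy = ent, sobel = sobel, laplace = lap,
       dog = dog, snr = snr)
}

#' Multi-feature interest-point score map
#'
#' Weighted sum of six min-max-normalized saliency maps: Harris response
#' (weight 0.25) plus local entropy, Sobel gradient magnitude, absolute
#' Laplacian, difference-of-Gaussians and local SNR (weight 0.15 each).
#' Weights must sum to 1, so the output lies in \[0,1\]. A constant feature
#' map contributes 0.
#'
#' @param img Enhanced 2-D image in \[0,1\].
#' @param weights Named numeric vector of the six weights (must sum to 1).
#' @param ... Passed to the internal feature computation (window sizes etc.).
#' @return Score matrix in \[0,1\]; the raw Harris response is attached as
#'   attribute `"harris"` (used to gate candidate points).
#' @export
score_map <- function(img, weights = c(harris = 0.25, entropy = 0.15,
                                       sobel = 0.15, laplace = 0.15,
                                       dog = 0.15, snr = 0.15), ...) {
  if (abs(sum(weights) - 1) > 1e-12) stop("score weights must sum to 1")
  feats <- saliency_features(img, ...)
  s <- img * 0
  for (nm in names(weights)) s <- s + weights[[nm]] * norm01(feats[[nm]])
  attr(s, "harris") <- feats$harris
  s
}

#' Extract spatially-spread top-K interest points from a score map
#'
#' Candidates are 3x3 local maxima with score at least `t` times the global
#' maximum (optionally gated to positive Harris response); they are accepted
#' in descending score order, rejecting any candidate closer than `d` pixels
#' to an already-accepted point, until `K` points are collected.
#'
#' @param score Score matrix in \[0,1\] (e.g. from [score_map()]).
#' @param t Relative threshold (default 0.02).
#' @param d Minimum spacing in pixels (default 6).
#' @param K Maximum number of points (default 100).
#' @param harris_gate Optional matrix (same shape): candidates must have a
#'   positive value in it (the dual role of the Harris detector).
#' @return An `interest_points` data frame with columns `x`, `y` (0-based,
#'   x = column) and `score`, sorted by descending score.
#' @export
extract_points <- function(score, t = 0.02, d = 6, K = 100L,
                           harris_gate = NULL) {
  score <- unclass(score)
  h <- nrow(score); w <- ncol(score)
  mx <- max(score)
  if (mx <= 0) {
    warning("all-zero score map: no interest points")
    return(structure(data.frame(x = integer(0), y = integer(0),
                                score = numeric(0)),
                     class = c("interest_points", "data.frame")))
  }
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- score
  ismax <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (score >= pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  ok <- ismax & (score >= t * mx)
  if (!is.null(harris_gate)) ok <- ok & (harris_gate > 0)
  idx <- which(ok)
  if (length(idx) == 0L)
    return(structure(data.frame(x = integer(0), y = integer(0),
                                score = numeric(0)),
                     class = c("interest_points", "data.frame")))
  ys <- (idx - 1) %% h      # 0-based row
  xs <- (idx - 1) %/% h     # 0-based col
  sc <- score[idx]
  ord <- order(-sc, ys, xs)
  ys <- ys[ord]; xs <- xs[ord]; sc <- sc[ord]
  keep_x <- numeric(0); keep_y <- numeric(0); keep_s <- numeric(0)
  for (i in seq_along(sc)) {
    if (length(keep_x) > 0 &&
        min((keep_x - xs[i])^2 + (keep_y - ys[i])^2) < d * d) next
    keep_x <- c(keep_x, xs[i]); keep_y <- c(keep_y, ys[i]); keep_s <- c(keep_s, sc[i])
    if (length(keep_x) >= K) break
  }
  structure(data.frame(x = as.integer(keep_x), y = as.integer(keep_y),
                       score = keep_s),
            class = c("interest_points", "data.frame"))
}

#' Detect interest points on a fused image
#'
#' Full chain: notch degrid, enhancement, score map, top-K extraction.
#'
#' @param fused A fused band image (matrix in any range; normalized
#'   internally).
#' @param K,t,d Extraction parameters, see [extract_points()].
#' @param gate_harris Gate candidates on positive Harris response.
#' @param ... Passed to [enhance()].
#' @return An `interest_points` data frame.
#' @export
detect_interest_points <- function(fused, K = 100L, t = 0.02, d = 6,
                                   gate_harris = TRUE, ...) {
  img <- norm01(unclass(fused))
  img <- notch_degrid(img)
  img <- pmin(pmax(img, 0), 1)
  img <- enhance(img, ...)
  s <- score_map(img)
  extract_points(s, t = t, d = d, K = K,
                 harris_gate = if (gate_harris) attr(s, "harris") else NULL)
}

#' Sample per-point reflectance spectra from a cube
#'
#' @param cube A [hyper_cube()].
#' @param points An `interest_points` data frame (0-based coordinates).
#' @return Numeric matrix, one row per point (in ranking order), one column
#'   per band.
#' @export
sample_spectra <- function(cube, points) {
  d <- dim(cube$values)
  if (nrow(points) == 0) return(matrix(numeric(0), 0, d[3]))
  if (any(points$x < 0 | points$x >= d[2] | points$y < 0 | points$y >= d[1]))
    stop("point outside cube bounds")
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  flat[points$y + 1L + d[1] * points$x, , drop = FALSE]
}
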