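# Band selection by fused similarity metrics.
#
# Four B x B band-similarity matrices (frequency-domain difference mapping,
# difference hash, normalized mutual information, SSIM) are min-max
# normalized and fused with equal weights; the complement drives greedy
# Max-Min selection of 10 representative bands, either with per-segment
# quotas (Strategy A) or a coverage-aware reward (Strategy B).

new_similarity <- function(values, metric) {
  diag(values) <- 1
  values <- (values + t(values)) / 2
  structure(values, metric = metric, class = c("similarity_matrix", "matrix", "array"))
}

#' Frequency-domain difference similarity matrix
#'
#' Per band, the log-magnitude of the 2-D FFT is computed; similarity
#' between two bands is `1 / (1 + mean |L_i - L_j|)` of those spectra
#' (identical bands give 1, diagonal forced to 1).
#'
#' @param cube A [hyper_cube()].
#' @return A B x B `similarity_matrix`.
#' @export
fddm_matrix <- function(cube) {
  v <- cube$values
  if (!all(is.finite(v))) stop("non-finite band data")
  d <- dim(v)
  B <- d[3]
  L <- matrix(0, d[1] * d[2], B)
  for (b in seq_len(B)) L[, b] <- as.vector(log1p(Mod(stats::fft(v[, , b]))))
  S <- matrix(0, B, B)
  for (i in seq_len(B)) S[, i] <- 1 / (1 + colMeans(abs(L - L[, i])))
  new_similarity(S, "FDDM")
}

# 64-bit difference hash of one band: resize to 8 rows x 9 cols, take the
# sign of the horizontal gradient. Constant bands hash to all-zero bits.
dhash_bits <- function(band) {
  small <- as.matrix(EBImage::resize(EBImage::Image(band), w = 8, h = 9))
  as.vector(small[, 2:9] > small[, 1:8])
}

#' Difference-hash similarity matrix
#'
#' Each band is resized to 9 x 8 and hashed to 64 horizontal-gradient-sign
#' bits; similarity is `1 - Hamming/64`, so values are quantized to
#' multiples of 1/64.
#'
#' @inheritParams fddm_matrix
#' @return A B x B `similarity_matrix`.
#' @export
dhash_matrix <- function(cube) {
  v <- cube$values
  B <- dim(v)[3]
  H <- vapply(seq_len(B), function(b) dhash_bits(v[, , b]), logical(64))
  Hn <- H * 1
  # Hamming distance via cross-products of bits and complements
  ones <- crossprod(Hn)            # both 1
  zeros <- crossprod(1 - Hn)       # both 0
  S <- (ones + zeros) / 64
  new_similarity(S, "DHASH")
}

#' Normalized mutual-information similarity matrix
#'
#' Joint histograms with 64 equal bins on \[0,1\]; similarity is
#' `MI(i,j) / min(H_i, H_j)` clipped to \[0,1\]. A zero-entropy band is
#' defined to have similarity 1 with itself and 0 with every other band.
#'
#' @inheritParams fddm_matrix
#' @param n_bins Number of histogram bins.
#' @return A B x B `similarity_matrix`.
#' @export
mi_matrix <- function(cube, n_bins = 64L) {
  v <- cube$values
  d <- dim(v); B <- d[3]; n <- d[1] * d[2]
  idx <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    bin <- floor(pmin(pmax(v[, , b], 0), 1 - 1e-12) * n_bins) + 1L
    idx[, b] <- bin
  }
  Hband <- numeric(B)
  for (b in seq_len(B)) {
    p <- tabulate(idx[, b], n_bins) / n
    p <- p[p > 0]
    Hband[b] <- -sum(p * log(p))
  }
  S <- diag(1, B)
  for (i in seq_len(B - 1L)) {
    for (j in (i + 1L):B) {
      if (Hband[i] <= 0 || Hband[j] <= 0) { S[i, j] <- S[j, i] <- 0; next }
      pj <- tabulate(idx[, i] + n_bins * (idx[, j] - 1L), n_bins * n_bins) / n
      pj <- pj[pj > 0]
      Hij <- -sum(pj * log(pj))
      mi <- Hband[i] + Hband[j] - Hij
      S[i, j] <- S[j, i] <- min(1, max(0, mi / min(Hband[i], Hband[j])))
    }
  }
  new_similarity(S, "MI")
}

# Separable Gaussian blur of every frame of an H x W x B array via banded
# matrix products (zero padding at the borders; callers crop the window
# half-width so border handling never reaches the averaged region).
band_blur_matrix <- function(n, g) {
  r <- (length(g) - 1L) %/% 2L
  Mb <- matrix(0, n, n)
  for (o in -r:r) {
    i <- max(1, 1 - o):min(n, n - o)
    Mb[cbind(i + o, i)] <- g[o + r + 1]
  }
  Mb
}

gauss_stack <- function(a, g) {
  d <- dim(a)
  Rb <- band_blur_matrix(d[1], g)
  Cb <- band_blur_matrix(d[2], g)
  out <- array(Rb %*% matrix(a, d[1]), d)               # along rows
  out <- aperm(array(Cb %*% matrix(aperm(out, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))        # along columns
  out
}

#' Structural-similarity (SSIM) matrix
#'
#' Mean SSIM per band pair with the standard constants: Gaussian window of
#' size 11 (sigma 1.5), K1 = 0.01, K2 = 0.03, data range 1. The window
#' half-width border is cropped before averaging so boundary handling does
#' not bias the score. Values clipped to \[0,1\].
#'
#' @inheritParams fddm_matrix
#' @return A B x B `similarity_matrix`.
#' @export
ssim_matrix <- function(cube) {
  v <- cube$values
  d <- dim(v); B <- d[3]
  if (d[1] < 11 || d[2] < 11) stop("bands must be at least 11 x 11 for SSIM")
  C1 <- 0.01^2; C2 <- 0.03^2
  g <- stats::dnorm(-5:5, sd = 1.5); g <- g / sum(g)
  pad <- 5L
  rows <- (pad + 1L):(d[1] - pad); cols <- (pad + 1L):(d[2] - pad)
  mu <- gauss_stack(v, g)
  m2 <- gauss_stack(v * v, g)
  vr <- m2 - mu * mu
  S <- diag(1, B)
  hw <- d[1] * d[2]
  for (i in seq_len(B)) {
    bi <- as.vector(v[, , i])
    Exy <- gauss_stack(array(as.vector(v) * bi, d), g)   # band i times every band
    mui <- as.vector(mu[, , i]); vari <- as.vector(vr[, , i])
    covij <- Exy - array(mui * as.vector(mu), d)
    num <- (2 * array(mui * as.vector(mu), d) + C1) * (2 * covij + C2)
    den <- (array(mui^2 + as.vector(mu)^2, d) + C1) *
           (array(vari + as.vector(vr), d) + C2)
    smap <- num / den
    S[i, ] <- colMeans(matrix(smap[rows, cols, , drop = FALSE],
                              length(rows) * length(cols), B))
  }
  S[S < 0] <- 0; S[S > 1] <- 1
  new_similarity(S, "SSIM")
}

#' Fuse similarity matrices into a combined similarity
#'
#' Each matrix is min-max normalized over its off-diagonal entries (a matrix
#' that is constant off the diagonal contributes 0.5 uniformly), then the
#' normalized matrices are combined as a weighted sum with weights summing
#' to 1 (default: equal weights 0.25). The diagonal is forced to 1.
#'
#' @param matrices List of B x B similarity matrices.
#' @param weights Non-negative weights, one per matrix, summing to 1.
#' @return A B x B `combined_similarity` matrix.
#' @export
combine_similarity <- function(matrices, weights = rep(1 / length(matrices),
                                                       length(matrices))) {
  stopifnot(length(matrices) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  B <- nrow(matrices[[1]])
  off <- !diag(TRUE, B)
  acc <- matrix(0, B, B)
  for (m in seq_along(matrices)) {
    M <- unclass(matrices[[m]])
    if (!identical(dim(M), c(B, B))) stop("matrices must share a common shape")
    lo <- min(M[off]); hi <- max(M[off])
    Mn <- if (hi > lo) (M - lo) / (hi - lo) else matrix(0.5, B, B)
    acc <- acc + weights[m] * Mn
  }
  acc <- (acc + t(acc)) / 2
  diag(acc) <- 1
  structure(acc, class = c("combined_similarity", "matrix", "array"))
}

#' Band difference matrix
#'
#' The complement `1 - S_comb` of a combined similarity: symmetric, zero
#' diagonal, values in \[0,1\].
#'
#' @param comb A `combined_similarity` matrix.
#' @return A B x B `difference_matrix`.
#' @export
difference_matrix <- function(comb) {
  d <- 1 - unclass(comb)
  d[d < 0] <- 0; d[d > 1] <- 1
  diag(d) <- 0
  structure(d, class = c("difference_matrix", "matrix", "array"))
}

#' Spectral segment (VIS / RED / NIR) of each band
#'
#' @param wavelengths A [wavelength_grid()].
#' @param boundaries Length-2 numeric: the VIS/RED and RED/NIR cut-offs in nm
#'   (default 620 and 700, the conventional red band).
#' @return Factor with levels `VIS`, `RED`, `NIR`.
#' @export
spectral_segments <- function(wavelengths, boundaries = c(620, 700)) {
  w <- unclass(wavelengths)
  factor(ifelse(w < boundaries[1], "VIS", ifelse(w < boundaries[2], "RED", "NIR")),
         levels = c("VIS", "RED", "NIR"))
}

#' Greedy Max-Min band selection
#'
#' If no bands are selected yet, the candidate with the largest row sum of
#' the difference matrix (over the candidate set) seeds the selection; then
#' the band with the largest minimum difference to the selected set is added
#' repeatedly until `quota` bands are selected. Ties break to the lowest
#' band index.
#'
#' @param delta A [difference_matrix()].
#' @param candidates Integer band indices to select from.
#' @param quota Number of bands to select (<= length(candidates)).
#' @param seeded Already-selected band indices (may be empty).
#' @return Integer vector of selected band indices, in selection order.
#' @export
maxmin_select <- function(delta, candidates, quota, seeded = integer(0)) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (quota > length(candidates)) stop("quota exceeds candidate count")
  delta <- unclass(delta)
  omega <- as.integer(seeded)
  picked <- integer(0)
  cand <- setdiff(as.integer(candidates), omega)
  while (length(picked) < quota) {
    if (length(omega) == 0L) {
      rs <- rowSums(delta[cand, cand, drop = FALSE])
      b <- cand[which.max(rs)]          # which.max takes the first (lowest) tie
    } else {
      md <- apply(delta[cand, omega, drop = FALSE], 1, min)
      b <- cand[which.max(md)]
    }
    omega <- c(omega, b)
    picked <- c(picked, b)
    cand <- setdiff(cand, b)
  }
  picked
}

new_band_set <- function(bands, strategy, wavelengths) {
  structure(list(bands = as.integer(bands),
                 wavelengths = wavelength_of(bands, wavelengths),
                 strategy = strategy, k = length(bands)),
            class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> strategy %s, k = %d\n", x$strategy, x$k))
  print(data.frame(band = x$bands, wavelength_nm = x$wavelengths))
  invisible(x)
}

#' Strategy A: per-segment quota Max-Min selection
#'
#' The grid is split into VIS/RED/NIR segments and [maxmin_select()] runs
#' independently inside each with quotas 3:3:4 (for k = 10). The union is
#' returned sorted ascending.
#'
#' @param delta A [difference_matrix()].
#' @param wavelengths A [wavelength_grid()] for the cube's bands.
#' @param quota Integer per-segment quotas (VIS, RED, NIR).
#' @param boundaries Segment cut-offs in nm, see [spectral_segments()].
#' @return A `band_set`.
#' @export
strategy_a <- function(delta, wavelengths, quota = c(3L, 3L, 4L),
                       boundaries = c(620, 700)) {
  seg <- spectral_segments(wavelengths, boundaries)
  sel <- integer(0)
  for (s in seq_along(levels(seg))) {
    cand <- which(seg == levels(seg)[s])
    if (length(cand) < quota[s])
      stop(sprintf("segment %s has %d bands, fewer than its quota %d",
                   levels(seg)[s], length(cand), quota[s]))
    sel <- c(sel, maxmin_select(delta, cand, quota[s]))
  }
  new_band_set(sort(sel), "A", wavelengths)
}

#' Strategy B: coverage-aware Max-Min selection
#'
#' Global greedy selection where a candidate's Max-Min score is multiplied
#' by `(1 + lambda_cov)` when its spectral segment is not yet represented in
#' the selected set. The seed is the global row-sum maximizer.
#'
#' @inheritParams strategy_a
#' @param lambda_cov Coverage reward factor (>= 0).
#' @param k Number of bands to select.
#' @return A `band_set` (bands in selection order).
#' @export
strategy_b <- function(delta, wavelengths, lambda_cov = 0.15, k = 10L,
                       boundaries = c(620, 700)) {
  if (lambda_cov < 0) stop("lambda_cov must be >= 0")
  delta <- unclass(delta)
  B <- nrow(delta)
  if (k > B) stop("k exceeds band count")
  seg <- spectral_segments(wavelengths, boundaries)
  cand <- seq_len(B)
  rs <- rowSums(delta)
  seedb <- cand[which.max(rs)]
  omega <- seedb
  covered <- as.character(seg[seedb])
  cand <- setdiff(cand, seedb)
  while (length(omega) < k) {
    md <- apply(delta[cand, omega, drop = FALSE], 1, min)
    reward <- ifelse(as.character(seg[cand]) %in% covered, 1, 1 + lambda_cov)
    score <- md * reward
    b <- cand[which.max(score)]
    omega <- c(omega, b)
    covered <- union(covered, as.character(seg[b]))
    cand <- setdiff(cand, b)
  }
  new_band_set(omega, "B", wavelengths)
}

#' Select representative bands from a cube
#'
#' Convenience wrapper: computes the four similarity matrices, fuses them
#' with equal weights, forms the difference matrix and runs the requested
#' strategy.
#'
#' @param cube A [hyper_cube()].
#' @param strategy `"A"` (partition quota) or `"B"` (coverage-aware).
#' @param weights Metric fusion weights (FDDM, DHASH, MI, SSIM).
#' @param lambda_cov Coverage reward for Strategy B.
#' @param k Number of bands (Strategy B; Strategy A uses `quota`).
#' @param quota Per-segment quotas for Strategy A.
#' @return A `band_set`; the fused difference matrix is attached as
#'   attribute `"delta"`.
#' @export
select_bands <- function(cube, strategy = c("A", "B"), weights = rep(0.25, 4),
                         lambda_cov = 0.15, k = 10L, quota = c(3L, 3L, 4L)) {
  strategy <- match.arg(strategy)
  mats <- list(fddm_matrix(cube), dhash_matrix(cube), mi_matrix(cube),
               ssim_matrix(cube))
  comb <- combine_similarity(mats, weights)
  delta <- difference_matrix(comb)
  bs <- if (strategy == "A") strategy_a(delta, cube$wavelengths, quota)
        else strategy_b(delta, cube$wavelengths, lambda_cov, k)
  attr(bs, "delta") <- delta
  bs
}
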