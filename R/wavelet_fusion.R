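# Multi-band image fusion by 2-level Daubechies-4 wavelet decomposition.
#
# The 1-D transform uses symmetric (half-sample) boundary extension and the
# redundant-length convention (out_len = floor((n + filter_len - 1)/2)),
# which makes the analysis/synthesis pair perfectly reconstructing for any
# signal length. Subband fusion: approximation coefficients averaged,
# detail coefficients taken by maximum absolute value.

DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
                -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
                -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- rev(DB4_DEC_LO)
DB4_REC_HI <- c(-0.010597401785069032, -0.0328830116668852, 0.030841381835560764,
                0.18703481171909309, -0.027983769416859854, -0.6308807679298589,
                0.7148465705529157, -0.2303778133088965)

# one analysis step along the first dimension of a matrix
dwt_step_rows <- function(M, filt) {
  fl <- length(filt)
  n <- nrow(M)
  ext <- rbind(M[(fl - 1):1, , drop = FALSE], M,
               M[n:(n - fl + 2), , drop = FALSE])
  ol <- (n + fl - 1) %/% 2
  out <- matrix(0, ol, ncol(M))
  base <- fl + 2 + 2 * (seq_len(ol) - 1)
  for (k in seq_len(fl)) out <- out + filt[k] * ext[base - k, , drop = FALSE]
  out
}

# one synthesis step along the first dimension; n_out = original length
idwt_step_rows <- function(A, D, n_out) {
  fl <- 8L
  la <- nrow(A)
  up <- function(M) {
    U <- matrix(0, 2 * la - 1, ncol(M))
    U[seq(1, by = 2, length.out = la), ] <- M
    U
  }
  UA <- up(A); UD <- up(D)
  ylen <- 2 * la - 1 + fl - 1
  y <- matrix(0, ylen, ncol(A))
  for (k in seq_len(fl)) {
    rows <- k:(k + 2 * la - 2)
    y[rows, ] <- y[rows, ] + DB4_REC_LO[k] * UA + DB4_REC_HI[k] * UD
  }
  y[(fl - 1):(fl - 2 + n_out), , drop = FALSE]
}

dwt2 <- function(M) {
  lo <- dwt_step_rows(M, DB4_DEC_LO)
  hi <- dwt_step_rows(M, DB4_DEC_HI)
  LL <- t(dwt_step_rows(t(lo), DB4_DEC_LO))
  LH <- t(dwt_step_rows(t(lo), DB4_DEC_HI))
  HL <- t(dwt_step_rows(t(hi), DB4_DEC_LO))
  HH <- t(dwt_step_rows(t(hi), DB4_DEC_HI))
  list(LL = LL, LH = LH, HL = HL, HH = HH, dim = dim(M))
}

idwt2 <- function(sb) {
  lo <- t(idwt_step_rows(t(sb$LL), t(sb$LH), sb$dim[2]))
  hi <- t(idwt_step_rows(t(sb$HL), t(sb$HH), sb$dim[2]))
  idwt_step_rows(lo, hi, sb$dim[1])
}

wavedec2 <- function(M, levels = 2L) {
  out <- vector("list", levels)
  cur <- M
  for (l in seq_len(levels)) {
    sb <- dwt2(cur)
    out[[l]] <- sb
    cur <- sb$LL
  }
  out
}

waverec2 <- function(dec) {
  levels <- length(dec)
  cur <- dec[[levels]]$LL
  for (l in rev(seq_len(levels))) {
    sb <- dec[[l]]
    sb$LL <- cur
    cur <- idwt2(sb)
  }
  cur
}

# elementwise maximum-absolute-value fusion across a list of matrices
fuse_maxabs <- function(mats) {
  out <- mats[[1]]
  for (k in seq_along(mats)[-1]) {
    take <- abs(mats[[k]]) > abs(out)
    out[take] <- mats[[k]][take]
  }
  out
}

#' Fuse several band images into one by wavelet subband rules
#'
#' Each image gets a 2-level db4 decomposition; the deepest approximation
#' subband is averaged across images and every detail subband is fused by
#' maximum absolute value; one inverse transform yields the fused image.
#' Fusing N copies of the same image returns that image (within float
#' tolerance), and the result is invariant to the input order.
#'
#' @param images List of numeric matrices with identical shapes (>= 2; a
#'   band-selection stage typically supplies 10).
#' @param levels Decomposition depth (default 2).
#' @return A numeric matrix of the input shape, with class `"fused_image"`.
#' @export
fuse_bands <- function(images, levels = 2L) {
  if (length(images) < 2L) stop("need at least 2 images to fuse")
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
    stop("images must share a common shape")
  if (min(d) < 16L) stop("images too small for a 2-level db4 decomposition")
  decs <- lapply(images, wavedec2, levels = levels)
  fused <- decs[[1]]
  for (l in seq_len(levels)) {
    for (band in c("LH", "HL", "HH"))
      fused[[l]][[band]] <- fuse_maxabs(lapply(decs, function(dc) dc[[l]][[band]]))
  }
  approx <- Reduce(`+`, lapply(decs, function(dc) dc[[levels]]$LL)) / length(decs)
  fused[[levels]]$LL <- approx
  out <- waverec2(fused)
  structure(out, class = c("fused_image", "matrix", "array"))
}

#' Extract the selected band images from a cube
#'
#' @param cube A [hyper_cube()].
#' @param band_set A `band_set` from [select_bands()] (or an integer vector).
#' @return List of band image matrices in band order.
#' @export
band_images <- function(cube, band_set) {
  idx <- if (inherits(band_set, "band_set")) band_set$bands else as.integer(band_set)
  lapply(idx, function(b) cube$values[, , b])
}

#' Linear 8-bit normalization of an image
#'
#' Maps the minimum to 0 and the maximum to 255 with round-half-up; a
#' constant image maps to all zeros.
#'
#' @param img Numeric matrix with finite values.
#' @return Integer matrix in 0..255.
#' @export
to_uint8 <- function(img) {
  if (!all(is.finite(img))) stop("image must be finite")
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(matrix(0L, nrow(img), ncol(img)))
  out <- floor((img - lo) / (hi - lo) * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}
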