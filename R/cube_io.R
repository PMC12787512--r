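#' Wavelength grid for a hyperspectral cube
#'
#' Linear wavelength calibration over the spectrometer range. The default
#' covers 372.53--1038.57 nm in 128 bands, the grid of the SOC710-VP style
#' cubes the rest of the package assumes.
#'
#' @param start_nm First band centre in nanometres.
#' @param end_nm Last band centre in nanometres.
#' @param n_bands Number of bands (>= 4).
#' @return Numeric vector of band-centre wavelengths with class
#'   `"wavelength_grid"`.
#' @export
#' @examples
#' g <- wavelength_grid()
#' wavelength_of(8, g)   # 409.24
wavelength_grid <- function(start_nm = 372.53, end_nm = 1038.57, n_bands = 128L) {
  n_bands <- as.integer(n_bands)
  if (n_bands < 4L) stop("n_bands must be >= 4")
  if (!(end_nm > start_nm)) stop("end_nm must exceed start_nm")
  w <- seq(start_nm, end_nm, length.out = n_bands)
  class(w) <- "wavelength_grid"
  w
}

#' Wavelength of a band index
#'
#' Maps a 1-based band index to its centre wavelength, reported to two
#' decimals (the precision band tables are printed at).
#'
#' @param index 1-based band index (vectorised).
#' @param grid A [wavelength_grid()].
#' @return Wavelength(s) in nm, rounded to 2 decimals.
#' @export
wavelength_of <- function(index, grid = wavelength_grid()) {
  index <- as.integer(index)
  if (any(index < 1L | index > length(grid))) stop("band index out of range")
  round(unclass(grid)[index], 2)
}

#' Construct a hyperspectral cube
#'
#' A cube is an H x W x B reflectance array (unitless, in \[0,1\] once
#' calibrated) plus its wavelength grid and an optional class label.
#'
#' @param values Numeric H x W x B array.
#' @param wavelengths A [wavelength_grid()] of length B (built automatically
#'   when omitted).
#' @param label Optional class label.
#' @return An object of class `"hyper_cube"`.
#' @export
hyper_cube <- function(values, wavelengths = NULL, label = NULL) {
  if (length(dim(values)) != 3L) stop("values must be an H x W x B array")
  d <- dim(values)
  if (d[1] < 8L || d[2] < 8L) stop("cube spatial size must be at least 8 x 8")
  if (is.null(wavelengths)) wavelengths <- wavelength_grid(n_bands = d[3])
  if (length(wavelengths) != d[3]) stop("wavelength grid length must equal band count")
  if (!all(is.finite(values))) stop("cube values must be finite")
  structure(list(values = values, wavelengths = wavelengths, label = label),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hyper_cube> %d x %d px, %d bands (%.2f-%.2f nm)%s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (is.null(x$label)) "" else paste0(", label: ", x$label)))
  invisible(x)
}

#' @export
dim.hyper_cube <- function(x) dim(x$values)

#' Reflectance calibration from white and dark references
#'
#' Standard flat-field calibration R = (raw - dark) / (white - dark), clipped
#' to \[0,1\]. Pixels where the white and dark frames coincide cannot be
#' calibrated and raise an error listing how many were flagged.
#'
#' @param raw,white,dark Numeric arrays of identical shape (H x W x B).
#' @param wavelengths Optional [wavelength_grid()].
#' @param label Optional class label for the result.
#' @return A calibrated [hyper_cube()].
#' @export
calibrate_reflectance <- function(raw, white, dark, wavelengths = NULL, label = NULL) {
  if (!identical(dim(raw), dim(white)) || !identical(dim(raw), dim(dark)))
    stop("raw, white and dark must have identical shapes")
  denom <- white - dark
  bad <- sum(denom <= 0)
  if (bad > 0)
    stop(sprintf("calibration undefined at %d pixel-band(s): white <= dark", bad))
  r <- (raw - dark) / denom
  r[r < 0] <- 0
  r[r > 1] <- 1
  hyper_cube(r, wavelengths, label)
}

#' Crop a cube to the inscribed rectangle of a circular region
#'
#' Wood cross-sections are circular; the axis-aligned square inscribed in the
#' circle (side `floor(radius * sqrt(2))`) removes the corner background. All
#' bands are cropped identically.
#'
#' @param cube A [hyper_cube()].
#' @param center Length-2 integer (row, col) of the circle centre, 1-based.
#' @param radius Circle radius in pixels (>= 6).
#' @return The cropped [hyper_cube()].
#' @export
crop_inscribed_rectangle <- function(cube, center, radius) {
  stopifnot(inherits(cube, "hyper_cube"), length(center) == 2L)
  if (radius < 6) stop("radius too small (must be >= 6)")
  d <- dim(cube$values)
  cr <- center[1]; cc <- center[2]
  if (cr - radius < 1 || cr + radius > d[1] || cc - radius < 1 || cc + radius > d[2])
    stop("circle exceeds the image frame")
  side <- floor(radius * sqrt(2))
  half <- side %/% 2
  rows <- seq(cr - half, length.out = side)
  cols <- seq(cc - half, length.out = side)
  hyper_cube(cube$values[rows, cols, , drop = FALSE], cube$wavelengths, cube$label)
}

# ENVI I/O ---------------------------------------------------------------
#
# Minimal ENVI dialect: ASCII .hdr + raw binary image file. Default written
# form is BSQ float32 little-endian with wavelengths in the header; BIL and
# BIP are also read and written. No installed R package reads ENVI pairs, so
# the format is handled here directly.

parse_envi_header <- function(hdr_path) {
  txt <- readLines(hdr_path, warn = FALSE)
  txt <- paste(txt, collapse = "\n")
  # join brace-delimited multi-line values
  fields <- list()
  pat <- gregexpr("([a-zA-Z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)", txt)[[1]]
  starts <- pat; lens <- attr(pat, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1)
    eq <- regexpr("=", piece)
    key <- tolower(trimws(substr(piece, 1, eq - 1)))
    val <- trimws(substr(piece, eq + 1, nchar(piece)))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI header/binary cube pair
#'
#' @param path Path to the `.hdr` file or its binary companion (either works;
#'   the pair is resolved by extension).
#' @return A [hyper_cube()].
#' @export
read_envi <- function(path) {
  if (grepl("\\.hdr$", path)) {
    hdr <- path
    img <- sub("\\.hdr$", ".img", path)
    if (!file.exists(img)) img <- sub("\\.hdr$", "", path)
  } else {
    img <- path
    hdr <- paste0(sub("\\.img$", "", path), ".hdr")
  }
  if (!file.exists(hdr)) stop("ENVI header not found: ", hdr)
  if (!file.exists(img)) stop("ENVI binary not found: ", img)
  f <- parse_envi_header(hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(f))
  if (length(miss)) stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  W <- as.integer(f[["samples"]]); H <- as.integer(f[["lines"]])
  B <- as.integer(f[["bands"]])
  dtype <- as.integer(f[["data type"]])
  if (!dtype %in% c(4L, 5L)) stop("unsupported ENVI data type: ", dtype)
  size <- if (dtype == 4L) 4L else 8L
  interleave <- tolower(f[["interleave"]])
  n <- as.numeric(W) * H * B
  actual <- file.size(img)
  if (actual != n * size)
    stop(sprintf("ENVI binary size mismatch: header implies %.0f bytes, file has %.0f",
                 n * size, actual))
  con <- file(img, "rb"); on.exit(close(con))
  v <- readBin(con, "double", n = n, size = size, endian = "little")
  vals <- switch(interleave,
    bsq = aperm(array(v, c(W, H, B)), c(2, 1, 3)),
    bil = aperm(array(v, c(W, B, H)), c(3, 1, 2)),
    bip = aperm(array(v, c(B, W, H)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  wl <- NULL
  if (!is.null(f[["wavelength"]])) {
    ws <- gsub("[{}]", "", f[["wavelength"]])
    wl <- as.numeric(strsplit(ws, ",")[[1]])
    if (length(wl) != B) stop("header wavelength count disagrees with bands")
    class(wl) <- "wavelength_grid"
  }
  hyper_cube(vals, wl)
}

#' Write a cube as an ENVI header/binary pair
#'
#' @param cube A [hyper_cube()].
#' @param path Output stem or `.hdr` path; `<stem>.hdr` and `<stem>.img` are
#'   written.
#' @param interleave One of `"bsq"`, `"bil"`, `"bip"`.
#' @return Invisibly, the `.hdr` path.
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  stem <- sub("\\.hdr$", "", path)
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {xylospec hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("wavelength = {%s}",
            paste(sprintf("%.10g", unclass(cube$wavelengths)), collapse = ", ")))
  writeLines(hdr, paste0(stem, ".hdr"))
  v <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1)))
  con <- file(paste0(stem, ".img"), "wb")
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  close(con)
  invisible(paste0(stem, ".hdr"))
}
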