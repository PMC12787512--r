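# Synthetic wood-cross-section hyperspectral cubes.
#
# Each species is a red-edge-like reflectance curve plus a cross-section
# texture model: growth rings as an oriented sinusoidal intensity field and
# vessels as dark disks from a seeded point process. The texture acts
# multiplicatively on the spectral curve, so ring/vessel structure shows up
# in every band, as it does in real cubes.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Deterministic per-item substream seed, kept below 2^31.
sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + k * 1013 + 1) %% 2147483647
  as.integer(s)
}

#' Species parameter sets for the synthetic generator
#'
#' Draws `n_classes` parameter sets. The pairing mode controls which fields
#' separate classes: in `"spectral_dominant"` mode consecutive class pairs
#' share identical texture parameters and differ only in the reflectance
#' curve; `"texture_dominant"` is the reverse; `"free"` draws everything
#' independently; `"mixed"` makes the first half of the classes a
#' spectral-dominant pair set and the second half texture-dominant (the
#' configuration used to study per-class fusion weights).
#'
#' @param n_classes Number of species (>= 2).
#' @param seed Integer seed; identical seeds give identical parameter sets.
#' @param mode Pairing mode, see above.
#' @param noise_sd Reflectance noise standard deviation shared by all species.
#' @return A list of `species_params` objects with fields
#'   `curve` (inflection_nm, slope_nm, base, plateau), `ring_frequency`
#'   (cycles per 100 px), `ring_orientation` (degrees), `ring_amplitude`,
#'   `vessel_density` (per 1000 px^2), `vessel_radius_px`, `noise_sd`.
#' @export
make_species <- function(n_classes, seed = 1L, mode = c("free", "spectral_dominant",
                                                        "texture_dominant", "mixed"),
                         noise_sd = 0.02) {
  mode <- match.arg(mode)
  if (n_classes < 2L) stop("need at least 2 classes")
  draw_curve <- function(i, spread) {
    list(inflection_nm = 650 + spread[i], slope_nm = runif(1, 18, 34),
         base = runif(1, 0.08, 0.2), plateau = runif(1, 0.55, 0.85))
  }
  draw_texture <- function(fr, or) {
    list(ring_frequency = fr, ring_orientation = or,
         ring_amplitude = runif(1, 0.25, 0.4),
         vessel_density = runif(1, 1.2, 3.2),
         vessel_radius_px = sample(2:4, 1))
  }
  with_seed(seed, {
    # well-separated deterministic anchors, jittered
    infl_spread <- seq(-60, 90, length.out = n_classes) + runif(n_classes, -5, 5)
    ring_fr <- seq(3.5, 11.5, length.out = n_classes) + runif(n_classes, -0.3, 0.3)
    ring_or <- (seq(0, 150, length.out = n_classes) + runif(n_classes, -8, 8)) %% 180
    half <- n_classes %/% 2
    kind <- switch(mode,
      free = rep("free", n_classes),
      spectral_dominant = rep("sd", n_classes),
      texture_dominant = rep("td", n_classes),
      mixed = c(rep("sd", half), rep("td", n_classes - half)))
    out <- vector("list", n_classes)
    for (i in seq_len(n_classes)) {
      cur <- draw_curve(i, infl_spread)
      tex <- draw_texture(ring_fr[i], ring_or[i])
      out[[i]] <- c(list(curve = cur), tex, list(noise_sd = noise_sd))
    }
    # enforce sharing within consecutive pairs
    for (i in seq_len(n_classes)) {
      if (i %% 2L == 0L) {
        mate <- i - 1L
        if (kind[i] == "sd" && kind[mate] == "sd") {
          out[[i]][c("ring_frequency", "ring_orientation", "ring_amplitude",
                     "vessel_density", "vessel_radius_px")] <-
            out[[mate]][c("ring_frequency", "ring_orientation", "ring_amplitude",
                          "vessel_density", "vessel_radius_px")]
        } else if (kind[i] == "td" && kind[mate] == "td") {
          out[[i]]$curve <- out[[mate]]$curve
        }
      }
    }
    lapply(out, function(p) structure(p, class = "species_params"))
  })
}

#' Reflectance curve of a species over a wavelength grid
#'
#' Red-edge-like sigmoid: base + (plateau - base) / (1 + exp(-(lambda -
#' inflection)/slope)). Values lie in \[0,1\] whenever base and plateau do.
#'
#' @param params A `species_params` object.
#' @param wavelengths A [wavelength_grid()] (nm).
#' @return Numeric reflectance vector, one value per band.
#' @export
species_curve <- function(params, wavelengths = wavelength_grid()) {
  cv <- params$curve
  w <- unclass(wavelengths)
  cv$base + (cv$plateau - cv$base) / (1 + exp(-(w - cv$inflection_nm) / cv$slope_nm))
}

# Multiplicative texture intensity field: rings (oriented sinusoid, random
# phase per cube) and vessels (factor 0.5 inside dark disks).
texture_field <- function(params, height, width) {
  th <- params$ring_orientation * pi / 180
  x <- matrix(rep(0:(width - 1), each = height), height, width)
  y <- matrix(rep(0:(height - 1), width), height, width)
  phase <- runif(1, 0, 2 * pi)
  u <- x * cos(th) + y * sin(th)
  m <- 1 + params$ring_amplitude * sin(2 * pi * params$ring_frequency / 100 * u + phase)
  n_ves <- rpois(1, params$vessel_density * height * width / 1000)
  if (n_ves > 0) {
    vx <- runif(n_ves, 1, width); vy <- runif(n_ves, 1, height)
    r <- params$vessel_radius_px
    for (k in seq_len(n_ves)) {
      rows <- max(1, floor(vy[k] - r)):min(height, ceiling(vy[k] + r))
      cols <- max(1, floor(vx[k] - r)):min(width, ceiling(vx[k] + r))
      dd <- outer((rows - vy[k])^2, (cols - vx[k])^2, "+")
      sub <- m[rows, cols, drop = FALSE]
      sub[dd <= r^2] <- sub[dd <= r^2] * 0.5
      m[rows, cols] <- sub
    }
  }
  m
}

#' Render one synthetic hyperspectral cube
#'
#' Per-pixel spectrum = species curve scaled by the local texture intensity
#' (rings + vessels) plus seeded Gaussian noise, clipped to \[0,1\].
#'
#' @param params A `species_params` object from [make_species()].
#' @param height,width,n_bands Cube dimensions (n_bands >= 4).
#' @param seed Integer seed; identical inputs give bitwise-identical cubes.
#' @param label Optional label stored on the cube.
#' @return A [hyper_cube()].
#' @export
render_cube <- function(params, height = 96L, width = 96L, n_bands = 128L,
                        seed = 1L, label = NULL) {
  if (n_bands < 4L) stop("n_bands must be >= 4")
  grid <- wavelength_grid(n_bands = n_bands)
  curve <- species_curve(params, grid)
  with_seed(seed, {
    m <- texture_field(params, height, width)
    vals <- array(as.vector(m) %o% curve, c(height, width, n_bands))
    if (params$noise_sd > 0)
      vals <- vals + rnorm(length(vals), 0, params$noise_sd)
    vals[vals < 0] <- 0
    vals[vals > 1] <- 1
    hyper_cube(vals, grid, label)
  })
}

#' Generate a labelled synthetic dataset
#'
#' @param n_classes,n_per_class Dataset layout; exactly `n_per_class` cubes
#'   per class are produced.
#' @param height,width,n_bands Cube dimensions.
#' @param seed Master seed; every cube's randomness derives from it.
#' @param mode Pairing mode, see [make_species()].
#' @param noise_sd Reflectance noise level.
#' @return List with `cubes` (list of [hyper_cube()]), `labels` (integer
#'   vector), and `species` (the parameter list).
#' @export
make_dataset <- function(n_classes = 4L, n_per_class = 20L, height = 96L,
                         width = 96L, n_bands = 128L, seed = 7L,
                         mode = "free", noise_sd = 0.02) {
  if (n_per_class < 1L) stop("n_per_class must be positive")
  sp <- make_species(n_classes, seed = seed, mode = mode, noise_sd = noise_sd)
  cubes <- vector("list", n_classes * n_per_class)
  labels <- integer(n_classes * n_per_class)
  k <- 0L
  for (ci in seq_len(n_classes)) {
    for (j in seq_len(n_per_class)) {
      k <- k + 1L
      cubes[[k]] <- render_cube(sp[[ci]], height, width, n_bands,
                                seed = sub_seed(seed, ci, j),
                                label = ci)
      labels[k] <- ci
    }
  }
  list(cubes = cubes, labels = labels, species = sp)
}

#' Add a periodic grid artifact to an intensity image
#'
#' Simulates the periodic interference fringes that imaging hardware can
#' imprint: `out = in + amplitude * sin(2 pi x / period) * sin(2 pi y /
#' period)`, clipped to \[0,1\] (x = column index, y = row index, 0-based).
#'
#' @param image 2-D numeric matrix in \[0,1\].
#' @param period_px Fringe period in pixels (>= 2).
#' @param amplitude Fringe amplitude.
#' @return The contaminated image, clipped to \[0,1\].
#' @export
add_grid_artifact <- function(image, period_px, amplitude) {
  if (period_px < 2) stop("period_px must be >= 2")
  h <- nrow(image); w <- ncol(image)
  sx <- sin(2 * pi * (0:(w - 1)) / period_px)
  sy <- sin(2 * pi * (0:(h - 1)) / period_px)
  out <- image + amplitude * (sy %o% sx)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
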