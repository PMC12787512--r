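# End-to-end orchestration: synthetic data -> band selection -> wavelet
# fusion -> interest points -> texture space -> branch training -> per-class
# fusion -> evaluation.

#' Default pipeline configuration
#'
#' Nested list mirroring the module boundaries. Every entry can be
#' overridden by passing a partial list to [run_pipeline()].
#'
#' @return Named nested list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    data = list(n_classes = 4L, n_per_class = 20L, height = 96L, width = 96L,
                n_bands = 128L, seed = 7L, mode = "mixed", noise_sd = 0.02,
                test_per_class = 5L),
    bands = list(strategy = "A", k = 10L, lambda_cov = 0.15,
                 quota = c(3L, 3L, 4L), crop = 64L),
    points = list(K = 100L, t = 0.02, d = 6),
    spectral = list(d = 64L, depth = 1L, heads = 4L, dropout = 0,
                    epochs = 14L, batch = 48L, lr = 5e-3,
                    points_per_sample = 8L, eval_points = 12L),
    texture = list(embed = 64L, mix = 32L, depth = 2L, heads = 4L,
                   window = 6L, patch = 4L, mlp_ratio = 2, se_ratio = 8L,
                   downsample = 2L, epochs = 6L, batch = 8L, lr = 1.5e-3,
                   n_keep = 32L, alpha = 0.7),
    fusion = list(beta = 5e-3, epochs = 150L, lr = 5e-2),
    out_dir = NULL,
    verbose = FALSE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Mean-pool a texture stack spatially
#'
#' @param stack H x W x C array.
#' @param factor Integer pooling factor (1 = unchanged).
#' @return Pooled array (H/factor x W/factor x C, truncated to multiples).
#' @export
downsample_stack <- function(stack, factor) {
  if (factor <= 1) return(stack)
  d <- dim(stack)
  H2 <- d[1] %/% factor; W2 <- d[2] %/% factor
  A <- array(stack[seq_len(H2 * factor), seq_len(W2 * factor), , drop = FALSE],
             c(factor, H2, factor, W2, d[3]))
  array(colMeans(matrix(aperm(A, c(1, 3, 2, 4, 5)), factor * factor)),
        c(H2, W2, d[3]))
}

scale_points <- function(points, factor) {
  if (factor <= 1 || nrow(points) == 0) return(points)
  points$x <- points$x / factor
  points$y <- points$y / factor
  points
}

#' Extract all per-sample features for the two branches
#'
#' Runs the feature stages for one cube: band-image wavelet fusion,
#' interest-point detection and spectral signatures, the texture feature
#' space with per-modality salient points, and the token-grid saliency
#' maps.
#'
#' @param cube A [hyper_cube()].
#' @param bands A `band_set`.
#' @param cfg Pipeline configuration (see [default_pipeline_config()]).
#' @return List with `fused`, `points`, `signatures`, `stack` (downsampled
#'   for the texture model), `saliency`.
#' @export
extract_features <- function(cube, bands, cfg = default_pipeline_config()) {
  fused <- fuse_bands(band_images(cube, bands))
  pts <- detect_interest_points(fused, K = cfg$points$K, t = cfg$points$t,
                                d = cfg$points$d)
  sig <- sample_spectra(cube, pts)
  ts <- texture_space(cube, fused, K = cfg$points$K)
  f <- cfg$texture$downsample
  stack <- downsample_stack(ts$stack, f)
  mp <- lapply(ts$points, scale_points, factor = f)
  tcfg <- texture_config(embed = cfg$texture$embed, mix = cfg$texture$mix,
                         depth = cfg$texture$depth, heads = cfg$texture$heads,
                         window = cfg$texture$window, patch = cfg$texture$patch,
                         mlp_ratio = cfg$texture$mlp_ratio,
                         se_ratio = cfg$texture$se_ratio,
                         n_classes = 2L)   # class count irrelevant here
  sal <- build_saliency(mp, dim(stack)[1:2], tcfg, alpha = cfg$texture$alpha,
                        n_keep = cfg$texture$n_keep)
  list(fused = fused, points = pts, signatures = sig, stack = stack,
       saliency = sal)
}

#' Run the full identification pipeline on synthetic data
#'
#' Generates a labelled synthetic dataset, selects bands once on the first
#' training cube, extracts per-sample features, trains the spectral and
#' texture branches and the per-class fusion weights, and evaluates all
#' three models on a held-out split. With `out_dir` set, artifacts
#' (band set, fusion weights, confusion matrices, manifest with file
#' hashes) are written as plain files.
#'
#' @param config Partial configuration merged over
#'   [default_pipeline_config()].
#' @return An `xylo_pipeline` object: accuracies, confusion matrices,
#'   fitted models, band set and the configuration used.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(default_pipeline_config(), config)
  dc <- cfg$data
  if (dc$test_per_class >= dc$n_per_class)
    stop("test_per_class must be smaller than n_per_class")
  vb <- isTRUE(cfg$verbose)
  say <- function(...) if (vb) message(sprintf(...))
  say("generating %d x %d cubes (%d classes)", dc$n_per_class, dc$n_classes,
      dc$n_classes)
  ds <- make_dataset(dc$n_classes, dc$n_per_class, dc$height, dc$width,
                     dc$n_bands, seed = dc$seed, mode = dc$mode,
                     noise_sd = dc$noise_sd)
  n <- length(ds$cubes)
  is_test <- rep(FALSE, n)
  for (ci in seq_len(dc$n_classes)) {
    idx <- which(ds$labels == ci)
    is_test[utils::tail(idx, dc$test_per_class)] <- TRUE
  }
  say("selecting bands (strategy %s)", cfg$bands$strategy)
  ref_cube <- ds$cubes[[which(!is_test)[1]]]
  cr <- cfg$bands$crop
  if (!is.null(cr) && cr < min(dc$height, dc$width)) {
    r0 <- (dc$height - cr) %/% 2; c0 <- (dc$width - cr) %/% 2
    ref_cube <- hyper_cube(ref_cube$values[(r0 + 1):(r0 + cr),
                                           (c0 + 1):(c0 + cr), , drop = FALSE],
                           ref_cube$wavelengths, ref_cube$label)
  }
  bands <- select_bands(ref_cube, strategy = cfg$bands$strategy,
                        lambda_cov = cfg$bands$lambda_cov, k = cfg$bands$k,
                        quota = cfg$bands$quota)
  say("extracting features for %d cubes", n)
  feats <- vector("list", n)
  for (i in seq_len(n)) feats[[i]] <- extract_features(ds$cubes[[i]], bands, cfg)
  sc <- cfg$spectral
  scfg <- spectral_config(n_bands = dc$n_bands, n_classes = dc$n_classes,
                          d = sc$d, depth = sc$depth, heads = sc$heads,
                          dropout = sc$dropout)
  tr <- which(!is_test); te <- which(is_test)
  Xtr <- do.call(rbind, lapply(tr, function(i)
    feats[[i]]$signatures[seq_len(min(sc$points_per_sample,
                                      nrow(feats[[i]]$signatures))), , drop = FALSE]))
  ytr <- unlist(lapply(tr, function(i)
    rep(ds$labels[i], min(sc$points_per_sample, nrow(feats[[i]]$signatures)))))
  say("training spectral branch on %d point spectra", nrow(Xtr))
  spec_model <- train_spectral(Xtr, ytr, scfg, epochs = sc$epochs,
                               batch_size = sc$batch, lr = sc$lr,
                               seed = dc$seed)
  tc <- cfg$texture
  tcfg <- texture_config(embed = tc$embed, mix = tc$mix, depth = tc$depth,
                         heads = tc$heads, window = tc$window,
                         patch = tc$patch, mlp_ratio = tc$mlp_ratio,
                         se_ratio = tc$se_ratio, n_classes = dc$n_classes)
  say("training texture branch on %d stacks", length(tr))
  tex_model <- train_texture(lapply(tr, function(i) feats[[i]]$stack),
                             lapply(tr, function(i) feats[[i]]$saliency),
                             ds$labels[tr], tcfg, epochs = tc$epochs,
                             batch_size = tc$batch, lr = tc$lr,
                             seed = dc$seed)
  ep <- sc$eval_points
  sig_of <- function(i) feats[[i]]$signatures[seq_len(min(ep,
    nrow(feats[[i]]$signatures))), , drop = FALSE]
  say("training fusion weights")
  fus <- st_former(spec_model, tex_model,
                   lapply(tr, sig_of),
                   lapply(tr, function(i) feats[[i]]$stack),
                   lapply(tr, function(i) feats[[i]]$saliency),
                   ds$labels[tr], beta = cfg$fusion$beta,
                   epochs = cfg$fusion$epochs, lr = cfg$fusion$lr)
  eval_split <- function(idx) {
    sigs <- lapply(idx, sig_of)
    stacks <- lapply(idx, function(i) feats[[i]]$stack)
    sal <- lapply(idx, function(i) feats[[i]]$saliency)
    truth <- ds$labels[idx]
    ps <- predict(spec_model, sigs)
    pt <- predict(tex_model, stacks, saliency = sal)
    pf <- predict(fus, sigs, stacks, saliency = sal)
    list(acc = c(spectral = mean(ps == truth), texture = mean(pt == truth),
                 fused = mean(pf == truth)),
         confusion = list(spectral = confusion_matrix(truth, ps, dc$n_classes),
                          texture = confusion_matrix(truth, pt, dc$n_classes),
                          fused = confusion_matrix(truth, pf, dc$n_classes)))
  }
  test_eval <- eval_split(te)
  say("test accuracy: spectral %.3f texture %.3f fused %.3f",
      test_eval$acc["spectral"], test_eval$acc["texture"], test_eval$acc["fused"])
  out <- structure(list(accuracy = test_eval$acc,
                        confusion = test_eval$confusion,
                        weights = fus$weights,
                        lambda_trajectory = fus$trajectory,
                        band_set = bands,
                        spectral = spec_model, texture = tex_model,
                        fusion = fus, labels = ds$labels, test_idx = te,
                        config = cfg),
                   class = "xylo_pipeline")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' @export
print.xylo_pipeline <- function(x, ...) {
  cat("<xylo_pipeline>\n")
  cat(sprintf("  bands (strategy %s): %s\n", x$band_set$strategy,
              paste(x$band_set$bands, collapse = ", ")))
  cat(sprintf("  test accuracy: spectral %.3f | texture %.3f | fused %.3f\n",
              x$accuracy["spectral"], x$accuracy["texture"], x$accuracy["fused"]))
  cat("  per-class texture weight sigmoid(lambda):",
      paste(round(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bands = file.path(out_dir, "bands.json"),
    weights = file.path(out_dir, "fusion_weights.json"),
    confusion = file.path(out_dir, "confusion_fused.csv"),
    accuracy = file.path(out_dir, "accuracy.json"))
  jsonlite::write_json(list(bands = res$band_set$bands,
                            wavelengths = res$band_set$wavelengths,
                            strategy = res$band_set$strategy),
                       paths["bands"], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(lambda = res$fusion$lambda,
                            weights = res$weights),
                       paths["weights"], digits = NA)
  utils::write.csv(res$confusion$fused, paths["confusion"], row.names = FALSE)
  jsonlite::write_json(as.list(res$accuracy), paths["accuracy"],
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = res$config$data$seed,
                   config = res$config[setdiff(names(res$config), "out_dir")],
                   files = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
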