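#' Experiment configuration
#'
#' Bundles every knob of the noise-robustness experiment: phantom geometry,
#' spectra, photon statistics, the decomposers to compare and the training
#' settings of the convolutional decomposer.  All randomness is derived
#' from the single `seed`.
#'
#' @param seed Master seed.
#' @param shape Phantom dimensions `c(height, width)` in pixels.
#' @param n_train Number of training phantoms for the convolutional
#'   decomposer; one additional held-out phantom is always generated for
#'   testing.
#' @param n_bone,n_tissue Structures per phantom.
#' @param pixel_size Pixel width, cm.
#' @param kvp_L,kvp_H Tube voltages of the two channels.
#' @param n_bins Energy bins per spectrum.
#' @param methods Decomposers to run, subset of
#'   `c("inverse", "iterative", "fcn")`.
#' @param noise Noise conditions to evaluate: any of `"noiseless"`,
#'   `"photon"`.
#' @param I_L,I_H Incident photons per ray for the photon-noise condition.
#' @param channel_scale,epochs,batch_size,stride Training settings of the
#'   convolutional decomposer (patches are extracted with this stride).
#' @param pad_patches Extract training patches with reflection padding so
#'   patch centers cover the whole phantom, including peripheral bone
#'   (see [extract_patches()]).
#' @param bone_oversample_stride Additional bone-centered patches are
#'   extracted on a sub-grid of this stride over each phantom's bone
#'   partition, counterbalancing how rare bone centers are on the uniform
#'   grid; `0` disables oversampling.
#' @param train_noise Train on noisy simulations (`TRUE`, default) or on
#'   noiseless ones.
#' @param iterative_lambda,iterative_iters Smoothness weight and step count
#'   of the iterative comparator.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L, shape = c(128L, 128L),
                              n_train = 10L, n_bone = 2L, n_tissue = 1L,
                              pixel_size = 0.1, kvp_L = 80, kvp_H = 140,
                              n_bins = 40L,
                              methods = c("inverse", "iterative", "fcn"),
                              noise = c("noiseless", "photon"),
                              I_L = 5e5, I_H = 1e6,
                              channel_scale = 0.25, epochs = 6L,
                              batch_size = 16L, stride = 13L,
                              pad_patches = TRUE,
                              bone_oversample_stride = 3L,
                              train_noise = TRUE,
                              iterative_lambda = 0.05,
                              iterative_iters = 80L) {
  known <- c("inverse", "iterative", "fcn")
  if (!all(methods %in% known))
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "), call. = FALSE)
  if (!all(noise %in% c("noiseless", "photon")))
    stop("`noise` entries must be 'noiseless' or 'photon'", call. = FALSE)
  structure(as.list(environment())[names(formals(experiment_config))],
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the
#' [experiment_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(experiment_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(experiment_config, vals)
}

simulate_for <- function(phantom, cfg, noisy, noise_seed) {
  simulate_dect(
    phantom,
    spec_L = make_spectrum(cfg$kvp_L, cfg$n_bins),
    spec_H = make_spectrum(cfg$kvp_H, cfg$n_bins),
    noise = if (noisy) list(I_L = cfg$I_L, I_H = cfg$I_H,
                            seed = noise_seed))
}

#' Calibrate the decomposition basis from a phantom simulation
#'
#' Simulates a noiseless scan of the calibration phantom and estimates the
#' effective basis from the eroded material partitions, normalized by the
#' known mean coefficient inside each ROI.
#'
#' @param phantom A ground-truth [material_image()].
#' @param img Optional pre-computed [dual_energy_image()] of the phantom;
#'   simulated noiselessly with the config spectra when omitted.
#' @param cfg An [experiment_config()].
#' @return A [basis2x2()].
#' @export
calibrate_basis <- function(phantom, img = NULL, cfg = experiment_config()) {
  if (is.null(img)) img <- simulate_for(phantom, cfg, FALSE, 0L)
  rois <- material_rois(phantom)
  estimate_basis(img, rois$tissue, rois$bone,
                 coef1 = mean(phantom$x1[rois$tissue]),
                 coef2 = mean(phantom$x2[rois$bone]))
}

#' Run the full decomposition comparison experiment
#'
#' Generates seeded training and held-out phantoms, simulates dual-energy
#' scans, calibrates the basis from a noiseless calibration scan, trains
#' the convolutional decomposer if requested, decomposes the held-out
#' phantom with every configured method under every noise condition, and
#' scores bias / SD per material ROI.
#'
#' @param cfg An [experiment_config()] (or a YAML path understood by
#'   [read_experiment_config()]).
#' @param out_dir Optional directory: decomposed and difference images are
#'   written as multi-page TIFF, the metric table as CSV and the run
#'   provenance (config and derived seeds) as YAML.
#' @param verbose Print progress.
#' @return A `dect_experiment` list: `metrics` (tibble with columns
#'   `method`, `material`, `noise`, `bias`, `sd`, `n`), `images` (nested
#'   list of decomposed [material_image()]s), `truth`, `basis`, `network`
#'   (or `NULL`) and `config`.
#' @export
run_experiment <- function(cfg = experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  say <- function(...) if (verbose) message(sprintf(...))

  data <- make_dataset(cfg$n_train, 1L, cfg$shape, seed = cfg$seed,
                       n_bone = cfg$n_bone, n_tissue = cfg$n_tissue,
                       pixel_size = cfg$pixel_size)
  truth <- data$test[[1L]]
  rois <- material_rois(truth)

  say("calibrating basis from phantom 1")
  basis <- calibrate_basis(data$train[[1L]], cfg = cfg)

  network <- NULL
  if ("fcn" %in% cfg$methods) {
    say("simulating %d training phantoms", cfg$n_train)
    sets <- lapply(seq_len(cfg$n_train), function(i) {
      img <- simulate_for(data$train[[i]], cfg, cfg$train_noise,
                          sub_seed(cfg$seed, 100L + i))
      grid <- extract_patches(img, data$train[[i]], stride = cfg$stride,
                              pad = cfg$pad_patches)
      bs <- cfg$bone_oversample_stride
      if (is.null(bs) || bs < 1L) return(grid)
      bone <- data$train[[i]]$x2 > 0
      keep <- bone
      keep[] <- FALSE
      sub <- seq.int(1L, nrow(bone), by = bs)
      keep[sub, sub] <- bone[sub, sub]
      if (!any(keep)) return(grid)
      extra <- extract_patches_at(img, data$train[[i]],
                                  which(keep, arr.ind = TRUE))
      merge_patch_sets(list(grid, extra))
    })
    patches <- merge_patch_sets(sets)
    say("training on %d patch pairs", dim(patches$low)[3])
    network <- fcn_train(patches,
                         fcn_config(channel_scale = cfg$channel_scale,
                                    epochs = cfg$epochs,
                                    batch_size = cfg$batch_size,
                                    seed = sub_seed(cfg$seed, 7L)),
                         verbose = verbose)
  }

  eval_mask <- rois$tissue | rois$bone
  metrics <- list(); images <- list()
  for (cond in cfg$noise) {
    noisy <- cond == "photon"
    img <- simulate_for(truth, cfg, noisy, sub_seed(cfg$seed, 999L))
    images[[cond]] <- list(input = img)
    for (method in cfg$methods) {
      say("decomposing (%s, %s)", method, cond)
      pred <- switch(method,
        inverse = invert_decompose(img, basis),
        iterative = iterative_decompose(img, basis,
                                        cfg$iterative_lambda,
                                        cfg$iterative_iters),
        fcn = decompose_image(network, img, pixels = eval_mask))
      sc <- score_decomposition(pred, truth, rois)
      sc$method <- method; sc$noise <- cond
      metrics[[paste(method, cond)]] <- sc
      images[[cond]][[method]] <- pred
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics <- metrics[, c("method", "material", "noise", "bias", "sd", "n")]
  rownames(metrics) <- NULL

  result <- structure(list(metrics = metrics, images = images,
                           truth = truth, basis = basis, network = network,
                           rois = rois, config = cfg),
                      class = "dect_experiment")
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.dect_experiment <- function(x, ...) {
  cat("<dect_experiment>\n")
  print(as.data.frame(x$metrics), digits = 4)
  invisible(x)
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  write_material_tiff(result$truth, file.path(out_dir, "truth.tif"))
  for (cond in names(result$images)) {
    for (nm in setdiff(names(result$images[[cond]]), "input")) {
      pred <- result$images[[cond]][[nm]]
      write_material_tiff(pred,
        file.path(out_dir, sprintf("decomposed_%s_%s.tif", nm, cond)))
      ok <- !is.na(pred$x1)
      diffi <- difference_image(
        structure(list(x1 = ifelse(ok, pred$x1, 0),
                       x2 = ifelse(ok, pred$x2, 0),
                       pixel_size = pred$pixel_size),
                  class = "material_image"),
        result$truth)
      write_material_tiff(diffi,
        file.path(out_dir, sprintf("difference_%s_%s.tif", nm, cond)))
    }
    write_dect_tiff(result$images[[cond]]$input,
                    file.path(out_dir, sprintf("input_%s.tif", cond)))
  }
  prov <- list(config = unclass(result$config),
               basis = result$basis[c("mu1H", "mu2H", "mu1L", "mu2L",
                                      "delta")],
               config_hash = config_hash(result$config))
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))),
             collapse = "\n")
  # small rolling hash; enough to fingerprint a config in the provenance log
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
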