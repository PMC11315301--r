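# End-to-end experiment orchestration: phantom data -> GAN ensemble ->
# (optional encoder) -> validation threshold sweep -> test detection and
# evaluation report.  Stages are cached on disk keyed by a content hash of
# their configuration and upstream artifacts, so re-running an identical
# configuration reuses every stage and reproduces the identical report.

#' Experiment configuration
#'
#' Bundles the nested stage configurations with a global seed.  The ensemble
#' members are trained with seeds `seed + 0, 1, 2, ...`; the phantom
#' populations of the train/validation/test/normal-evaluation splits use
#' disjoint seed offsets so no phantom "patient" ever appears in two splits.
#'
#' @param seed global experiment seed.
#' @param outdir output/cache directory.
#' @param resolution working resolution (propagated to all stages).
#' @param mode reconstruction mode, "restore" or "encoder".
#' @param n_train,n_val,n_test,n_normal_eval split sizes.
#' @param gan a [gan_config()] (its resolution/seed are overridden).
#' @param encoder an [encoder_config()] (used in encoder mode).
#' @param restore a [restoration_config()].
#' @param anomaly an [anomaly_config()].
#' @param phantom a [phantom_spec()] template (resolution/seed overridden).
#' @param lesion_kind,lesion_radius_frac,lesion_delta lesion population.
#' @param thresholds operating-point sweep grid (byte scale).
#' @param cache reuse cached stage artifacts when present.
#' @export
run_config <- function(seed = 1, outdir = tempfile("pseudohealthy_run_"),
                       resolution = 512, mode = c("restore", "encoder"),
                       n_train = 1180, n_val = 27, n_test = 26,
                       n_normal_eval = 25,
                       gan = gan_config(resolution = resolution),
                       encoder = encoder_config(),
                       restore = restoration_config(),
                       anomaly = anomaly_config(residual_kind = "positive_part"),
                       phantom = phantom_spec(resolution = resolution),
                       lesion_kind = "bright_blob",
                       lesion_radius_frac = c(0.08, 0.12),
                       lesion_delta = c(0.25, 0.40),
                       thresholds = 0:255, cache = TRUE) {
  mode <- match.arg(mode)
  gan$resolution <- resolution
  phantom$resolution <- resolution
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1, n_normal_eval >= 1)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 resolution = resolution, mode = mode, n_train = n_train,
                 n_val = n_val, n_test = n_test,
                 n_normal_eval = n_normal_eval, gan = gan, encoder = encoder,
                 restore = restore, anomaly = anomaly, phantom = phantom,
                 lesion_kind = lesion_kind,
                 lesion_radius_frac = lesion_radius_frac,
                 lesion_delta = lesion_delta, thresholds = thresholds,
                 cache = cache), class = "run_config")
}

#' Desk-scale experiment configuration
#'
#' The built-in small-scale study: 32x32 phantoms, a 64-dimensional latent
#' space, narrow networks, a 3-model ensemble trained 2000 steps each, and
#' latent restoration (200 steps per image).  These sizes make the complete
#' pipeline run on a single CPU while preserving every structural element of
#' the full-scale method.
#'
#' @param seed global experiment seed.
#' @param outdir output/cache directory.
#' @param gan_steps,restore_steps training/restoration step counts.
#' @param n_train,n_val,n_test,n_normal_eval split sizes.
#' @param mode reconstruction mode.
#' @param cache reuse cached stage artifacts.
#' @export
demo_run_config <- function(seed = 1, outdir = tempfile("pseudohealthy_run_"),
                            gan_steps = 2000, restore_steps = 200,
                            n_train = 64, n_val = 8, n_test = 20,
                            n_normal_eval = 8, mode = "restore",
                            cache = TRUE) {
  resolution <- 32L
  run_config(
    seed = seed, outdir = outdir, resolution = resolution, mode = mode,
    n_train = n_train, n_val = n_val, n_test = n_test,
    n_normal_eval = n_normal_eval,
    gan = gan_config(resolution = resolution, latent_dim = 64,
                     steps = gan_steps, base_channels = 4, channel_cap = 64,
                     seed = seed),
    encoder = encoder_config(steps = 1500, base_channels = 8,
                             channel_cap = 64, seed = seed),
    restore = restoration_config(steps = restore_steps, lr = 0.05),
    anomaly = anomaly_config(residual_kind = "positive_part"),
    phantom = phantom_spec(resolution = resolution, seed = seed),
    cache = cache)
}

.stage <- function(config, name, deps_key, payload_fn) {
  key <- digest::digest(list(name, deps_key))
  file <- file.path(config$outdir, sprintf("cache_%s_%s.rds", name,
                                           substr(key, 1, 12)))
  if (config$cache && file.exists(file)) return(readRDS(file))
  value <- payload_fn()
  saveRDS(value, file)
  value
}

.experiment_data <- function(config) {
  sp <- config$phantom
  sp_train <- sp; sp_train$seed <- config$seed
  sp_val <- sp; sp_val$seed <- config$seed + 1000L
  sp_test <- sp; sp_test$seed <- config$seed + 2000L
  sp_norm <- sp; sp_norm$seed <- config$seed + 3000L
  list(train = generate_phantom(sp_train, config$n_train, "train"),
       validation = phantom_with_lesions(sp_val, config$n_val,
                                         config$lesion_kind,
                                         config$lesion_radius_frac,
                                         config$lesion_delta, "validation"),
       test = phantom_with_lesions(sp_test, config$n_test,
                                   config$lesion_kind,
                                   config$lesion_radius_frac,
                                   config$lesion_delta, "test"),
       normal_eval = generate_phantom(sp_norm, config$n_normal_eval, "test"))
}

# per-model reconstructions for every image of a dataset
.ensemble_reconstructions <- function(dataset, models, config) {
  lapply(dataset$images, function(x)
    lapply(models, function(m)
      reconstruct_image(unclass(x), m, mode = config$mode,
                        restore_cfg = config$restore)))
}

# derive per-model byte-scale residual lists from reconstructions
.residuals_from <- function(dataset, recons, config) {
  lapply(seq_along(recons), function(i)
    lapply(recons[[i]], function(xh)
      residual_map(unclass(dataset$images[[i]]), xh,
                   config$anomaly$residual_kind, "byte")))
}

#' Run the full experiment
#'
#' Executes data generation, ensemble GAN training, optional encoder
#' training, validation threshold sweep, test-set detection and evaluation,
#' writing `report.json`, `sweep.csv` and `roc.csv` into the configured
#' output directory.  Stages already cached for an identical configuration
#' are reused; re-running an identical configuration reproduces the
#' identical report.
#'
#' @param config a [run_config()] or [demo_run_config()].
#' @return the report, invisibly a list (also written as JSON).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_core <- config[setdiff(names(config), c("outdir", "cache"))]

  data_key <- cfg_core[c("seed", "resolution", "phantom", "n_train", "n_val",
                         "n_test", "n_normal_eval", "lesion_kind",
                         "lesion_radius_frac", "lesion_delta")]
  data <- .stage(config, "data", data_key, function() .experiment_data(config))

  model_key <- list(data_key, cfg_core$gan, cfg_core$mode, cfg_core$encoder)
  models <- .stage(config, "models", model_key, function() {
    lapply(seq_len(config$anomaly$ensemble_size), function(k) {
      gk <- config$gan
      gk$seed <- config$seed + (k - 1L)
      model <- train_gan(data$train, gk)
      if (config$mode == "encoder") {
        ek <- config$encoder
        ek$seed <- config$seed + (k - 1L)
        model$encoder <- train_encoder(data$train, model$generator, ek)
      }
      model
    })
  })

  sweep_key <- list(model_key, cfg_core$restore, cfg_core$anomaly,
                    cfg_core$thresholds)
  sweep <- .stage(config, "sweep", sweep_key, function() {
    res_val <- .residuals_from(data$validation,
                               .ensemble_reconstructions(data$validation,
                                                         models, config),
                               config)
    radius <- if (is.null(config$anomaly$closing_radius))
      default_closing_radius(config$resolution) else config$anomaly$closing_radius
    sw <- sweep_operating_point(res_val, data$validation$masks,
                                config$thresholds, "median", radius)
    sw$closing_radius <- radius
    sw
  })

  eval_key <- list(sweep_key, "eval")
  evalr <- .stage(config, "eval", eval_key, function() {
    acfg <- config$anomaly
    acfg$threshold <- sweep$threshold
    acfg$closing_radius <- sweep$closing_radius
    recons_test <- .ensemble_reconstructions(data$test, models, config)
    res_test <- .residuals_from(data$test, recons_test, config)
    masks <- lapply(res_test, .mask_at, t = acfg$threshold,
                    closing_radius = acfg$closing_radius)
    dice_img <- vapply(seq_along(masks), function(i)
      as.numeric(dice(masks[[i]], data$test$masks[[i]])), numeric(1))
    lesions <- unlist(lapply(seq_along(masks), function(i)
      lesion_dice(masks[[i]], data$test$masks[[i]])))
    roc <- roc_curve(res_test, data$test$masks, config$thresholds)
    # ensemble-mean reconstructions for the error statistics (test-set
    # reconstructions are reused, only the normal group is computed here)
    mean_recon <- function(rs) lapply(rs, function(xs) Reduce(`+`, xs) / length(xs))
    rec_abn <- mean_recon(recons_test)
    rec_norm <- mean_recon(.ensemble_reconstructions(data$normal_eval,
                                                     models, config))
    stats <- reconstruction_stats(
      c(lapply(data$normal_eval$images, unclass),
        lapply(data$test$images, unclass)),
      c(rec_norm, rec_abn),
      c(rep("normal", length(rec_norm)), rep("abnormal", length(rec_abn))))
    list(threshold = acfg$threshold, dice = dice_img,
         lesion_dice = as.numeric(lesions),
         detection_rate = detection_rate(lesions),
         roc = roc, recon_stats = stats, masks = masks)
  })

  report <- list(
    seed = config$seed,
    resolution = config$resolution,
    mode = config$mode,
    n = list(train = config$n_train, validation = config$n_val,
             test = config$n_test, normal_eval = config$n_normal_eval),
    ensemble_size = config$anomaly$ensemble_size,
    residual_kind = config$anomaly$residual_kind,
    operating_threshold = evalr$threshold,
    validation_median_dice = max(sweep$sweep$median_dice),
    test = list(median_dice = stats::median(evalr$dice),
                mean_dice = mean(evalr$dice),
                sd_dice = stats::sd(evalr$dice),
                dice = evalr$dice,
                n_lesions = length(evalr$lesion_dice),
                detection_rate = evalr$detection_rate),
    reconstruction = split(evalr$recon_stats[-1], evalr$recon_stats$group),
    roc_auc = roc_auc(evalr$roc))

  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(sweep$sweep, file.path(config$outdir, "sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(evalr$roc, file.path(config$outdir, "roc.csv"),
                   row.names = FALSE)
  invisible(report)
}
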