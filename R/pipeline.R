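# End-to-end orchestration: fixtures -> preprocess -> train -> train-meta ->
# predict (TTA) -> ensemble, driven by a single config (R list or YAML file)
# with one seed.  Each stage writes its artifacts under the configured
# output directory and can be re-run independently; a missing upstream
# artifact produces an error naming the stage to run first.

#' Default experiment configuration
#'
#' Returns the full configuration list used by [run_pipeline()], with every
#' field overridable through `...` (or by editing the YAML written by
#' [write_experiment_config()]).
#'
#' @param out_dir artifact directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param ... fields to override (same names as in the returned list).
#' @return configuration list of class `experiment_config`.
#' @export
experiment_config <- function(out_dir, seed = 1L, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    # fixtures
    n_lesions = 60L, images_per_lesion = c(1L, 3L),
    image_size = c(96L, 96L), fov_radius_range = c(0.8, 0.95),
    metadata_missing_rates = c(age = 0.1, site = 0.1, sex = 0.1),
    image_class_signal = TRUE, metadata_class_signal = FALSE,
    # preprocessing
    binarize_threshold = 20 / 255, contrast_ratio = 2,
    min_outside_fraction = 0.05, sog_p = 6, resize_target = 64L,
    # training
    n_folds = 5L, folds = NULL, input_size = c(48L, 48L),
    strategy = "same_sized", epochs = 10L, base_lr = 1e-3, batch_size = 32L,
    eval_period = 5L, lr_halving_period = 25L, k = 1,
    # meta stage
    with_meta = FALSE, meta_epochs = 10L, meta_lr = 0.01,
    meta_batch_size = 20L, meta_p_drop = 0.1, fusion_units = 128L,
    # prediction / ensembling
    configs = list(list(name = "tiny_ss", strategy = "same_sized")),
    max_configs = 16L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  abort_if(length(unknown) > 0,
           paste("unknown config fields:", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg an [experiment_config()].
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  abort_if(is.null(raw$out_dir), "config must name an out_dir")
  do.call(experiment_config,
          c(list(out_dir = raw$out_dir, seed = raw$seed %||% 1L),
            raw[setdiff(names(raw), c("out_dir", "seed"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_experiment_config
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_artifact <- function(path, stage) {
  abort_if(!file.exists(path),
           sprintf("missing artifact '%s'; run stage '%s' first", path, stage))
  readRDS(path)
}

derive_seed <- function(seed, offset) (seed * 7919L + offset) %% (2^31 - 1)

#' Run the experiment pipeline
#'
#' Executes the requested stages in order on one synthetic dataset:
#' `"fixtures"` (generate images + metadata), `"preprocess"` (FOV crop,
#' color constancy, resize), `"train"` (stage-1 CNNs per fold and
#' configuration), `"train_meta"` (stage-2 metadata branch, when
#' `with_meta`), `"predict"` (TTA predictions per configuration and fold on
#' the held-out images), `"ensemble"` (exhaustive subset search +
#' best/last pooling), `"report"`.  Every artifact is written under
#' `cfg$out_dir` and is a deterministic function of the config and seed.
#'
#' @param cfg an [experiment_config()] (or a YAML path).
#' @param stages stages to run, in pipeline order.
#' @return invisibly, a list with the selection and report when those stages
#'   ran, else `NULL`.
#' @export
run_pipeline <- function(cfg, stages = c("fixtures", "preprocess", "train",
                                         "predict", "ensemble", "report")) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  abort_if(!inherits(cfg, "experiment_config"), "cfg must be an experiment_config")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, c("fixtures", "preprocess", "train", "train_meta",
                                "predict", "ensemble", "report"),
                      several.ok = TRUE)
  abort_if("train_meta" %in% stages && !isTRUE(cfg$with_meta),
           "config does not enable the meta stage (set with_meta: true)")
  result <- list()

  if ("fixtures" %in% stages) {
    spec <- synthetic_dataset_spec(
      n_lesions = cfg$n_lesions, images_per_lesion = cfg$images_per_lesion,
      metadata_missing_rates = cfg$metadata_missing_rates,
      image_size = cfg$image_size, fov_radius_range = cfg$fov_radius_range,
      image_class_signal = cfg$image_class_signal,
      metadata_class_signal = cfg$metadata_class_signal,
      seed = derive_seed(cfg$seed, 1L))
    ds <- gen_lesion_dataset(spec)
    saveRDS(ds, stage_path(cfg, "dataset.rds"))
    write_lesion_dataset(ds, stage_path(cfg, "fixtures"))
  }

  if ("preprocess" %in% stages) {
    ds <- require_artifact(stage_path(cfg, "dataset.rds"), "fixtures")
    params <- crop_params(cfg$binarize_threshold, cfg$contrast_ratio,
                          cfg$min_outside_fraction)
    log_rows <- list()
    for (i in seq_along(ds$records)) {
      pp <- preprocess(ds$records[[i]], params, sog_p = cfg$sog_p,
                       target = cfg$resize_target)
      ds$records[[i]] <- pp$image
      log_rows[[i]] <- data.frame(
        image = pp$image$image_id, cropped = pp$cropped,
        x0 = pp$box$x0 %||% NA, y0 = pp$box$y0 %||% NA,
        x1 = pp$box$x1 %||% NA, y1 = pp$box$y1 %||% NA)
    }
    saveRDS(ds, stage_path(cfg, "preprocessed.rds"))
    write.csv(do.call(rbind, log_rows), stage_path(cfg, "preprocess_log.csv"),
              row.names = FALSE)
  }

  if (any(c("train", "train_meta", "predict") %in% stages)) {
    ds <- require_artifact(stage_path(cfg, "preprocessed.rds"), "preprocess")
    split <- grouped_kfold(ds$lesion_ids, n_folds = cfg$n_folds,
                           seed = derive_seed(cfg$seed, 2L))
    folds <- cfg$folds %||% seq_len(cfg$n_folds)
  }

  if ("train" %in% stages) {
    ckpts <- list()
    for (ci in seq_along(cfg$configs)) {
      cc <- cfg$configs[[ci]]
      tc <- train_config(epochs = cfg$epochs, base_lr = cfg$base_lr,
                         batch_size = cfg$batch_size,
                         lr_halving_period = cfg$lr_halving_period,
                         eval_period = cfg$eval_period, k = cfg$k,
                         strategy = cc$strategy %||% cfg$strategy,
                         seed = derive_seed(cfg$seed, 10L + ci))
      ckpts[[cc$name]] <- train_cnn(ds, split, tc,
                                    backbone = tiny_backbone(cfg$input_size),
                                    folds = folds)
    }
    saveRDS(list(split = split, ckpts = ckpts), stage_path(cfg, "checkpoints.rds"))
  }

  if ("train_meta" %in% stages) {
    abort_if(!isTRUE(cfg$with_meta), "config does not enable the meta stage (with_meta)")
    abort_if(is.null(ds$meta), "meta stage requires a metadata table in the dataset")
    tr <- require_artifact(stage_path(cfg, "checkpoints.rds"), "train")
    mc <- meta_train_config(epochs = cfg$meta_epochs, lr = cfg$meta_lr,
                            batch_size = cfg$meta_batch_size,
                            p_drop = cfg$meta_p_drop,
                            seed = derive_seed(cfg$seed, 30L))
    mspec <- meta_branch_spec(fusion_units = cfg$fusion_units)
    meta_ckpts <- lapply(tr$ckpts, function(ck)
      train_meta(ds, tr$split, ck, mc, meta_spec = mspec))
    saveRDS(meta_ckpts, stage_path(cfg, "checkpoints_meta.rds"))
  }

  if ("predict" %in% stages) {
    tr <- require_artifact(stage_path(cfg, "checkpoints.rds"), "train")
    use_meta <- isTRUE(cfg$with_meta) &&
      file.exists(stage_path(cfg, "checkpoints_meta.rds"))
    all_ck <- if (use_meta) readRDS(stage_path(cfg, "checkpoints_meta.rds"))
              else tr$ckpts
    meta_records <- if (use_meta) read_isic_metadata(ds$meta)
    tensors <- list()
    for (kind in c("best", "last")) {
      preds <- lapply(all_ck, function(ck) {
        lapply(folds, function(j) {
          fi <- cv_fold_indices(tr$split, j)
          model <- model_from_checkpoint(ck, j, use = kind)
          strat <- if (identical(ck$config$strategy, "random_resize"))
            "random_resize" else "same_sized"
          if (inherits(ck$config, "meta_train_config")) strat <- "same_sized"
          do.call(rbind, lapply(fi$val, function(ii) {
            mv <- if (use_meta) encode_metadata(meta_records[[ii]])
            tta_predict(model, ds$records[[ii]]$image, mv, strat)$probs
          }))
        })
      })
      labels <- lapply(folds, function(j) ds$labels[cv_fold_indices(tr$split, j)$val])
      tensors[[kind]] <- prediction_tensor(preds, labels, names(all_ck))
    }
    saveRDS(tensors, stage_path(cfg, "prediction_tensors.rds"))
  }

  if ("ensemble" %in% stages) {
    tensors <- require_artifact(stage_path(cfg, "prediction_tensors.rds"), "predict")
    sel <- exhaustive_subset_search(tensors$best, max_configs = cfg$max_configs)
    final <- pool_best_last(sel, tensors$best, tensors$last)
    saveRDS(list(selection = sel, final = final), stage_path(cfg, "selection.rds"))
    result$selection <- sel
    result$final <- final
  }

  if ("report" %in% stages) {
    sel <- require_artifact(stage_path(cfg, "selection.rds"), "ensemble")
    tensors <- require_artifact(stage_path(cfg, "prediction_tensors.rds"), "predict")
    probs <- do.call(rbind, sel$final$y_final)
    truth <- unlist(tensors$best$labels)
    rep_df <- suppressWarnings(per_class_report(truth, probs))
    report <- list(selection = sel$selection$config_names,
                   S_star = sel$selection$S_star,
                   per_fold_S = sel$selection$per_fold_S,
                   S_final_best_last = sel$final$S,
                   per_class = rep_df, seed = cfg$seed)
    saveRDS(report, stage_path(cfg, "report.rds"))
    utils::capture.output(print(report), file = stage_path(cfg, "report.txt"))
    result$report <- report
  }

  invisible(if (length(result)) result else NULL)
}
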