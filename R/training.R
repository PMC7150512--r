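# Class-balanced two-stage training with lesion-grouped cross-validation.
#
# Stage 1 trains the CNN on images only with a weighted cross-entropy loss
# (weights (N/N_i)^k counter the severe class imbalance of dermoscopy
# datasets), Adam, a learning rate halved every 25 epochs, periodic
# evaluation of the mean sensitivity on the held-out fold, and best/last
# checkpointing.  Stage 2 freezes the CNN and trains only the metadata
# branch, fusion layer and classifier, with metadata dropout and the image
# augmentation still active (so CNN features vary between passes).

#' Per-class loss weights from class frequencies
#'
#' `n_i = (N / N_i)^k` with `N = sum(N_i)`: rarer classes get larger weights;
#' `k = 0` disables balancing, `k = 1` (the default) weights inversely to
#' frequency.  At `k = 1` the identity `sum(N_i * n_i) = C * N` holds.
#'
#' @param counts positive per-class image counts.
#' @param k balancing-severity exponent (default 1).
#' @return list of class `class_weights` with `counts`, `k`, `weights`.
#' @export
class_weights <- function(counts, k = 1) {
  abort_if(length(counts) < 2, "need at least two classes")
  abort_if(any(counts <= 0), "cannot weight a class with zero images")
  N <- sum(counts)
  structure(list(counts = as.numeric(counts), k = k,
                 weights = (N / counts)^k),
            class = "class_weights")
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `n_y * (-log p_y)` where `n_y` is the weight of the
#' sample's true class.  Also returns the gradient with respect to the
#' logits for use in training.
#'
#' @param logits `n x C` matrix of unnormalized scores.
#' @param labels integer vector of true classes in `0..C-1`, one per row.
#' @param weights a [class_weights()] object, or a plain numeric vector of
#'   per-class weights.
#' @return list with `loss` (scalar) and `dlogits` (`n x C`).
#' @export
weighted_cross_entropy <- function(logits, labels, weights) {
  w <- if (inherits(weights, "class_weights")) weights$weights else as.numeric(weights)
  n <- nrow(logits); K <- ncol(logits)
  abort_if(length(labels) != n, "one label per logit row required")
  abort_if(any(labels < 0 | labels >= K), "labels out of range")
  abort_if(length(w) != K, "weights must cover all classes")
  p <- softmax_rows(logits)
  ii <- cbind(seq_len(n), labels + 1L)
  wv <- w[labels + 1L]
  loss <- mean(wv * (-log(pmax(p[ii], 1e-12))))
  onehot <- matrix(0, n, K)
  onehot[ii] <- 1
  dlogits <- (p - onehot) * (wv / n)
  list(loss = loss, dlogits = dlogits)
}

#' Learning rate schedule: halve every fixed period
#'
#' `lr = base_lr * 0.5^floor(epoch / period)`, epochs counted from 0.
#'
#' @param epoch epoch index (>= 0).
#' @param base_lr initial learning rate.
#' @param period halving period in epochs (default 25).
#' @return learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, base_lr, period = 25L) {
  abort_if(any(epoch < 0), "epoch must be >= 0")
  base_lr * 0.5^(epoch %/% period)
}

#' Lesion-grouped k-fold split
#'
#' Partitions lesions (not images) into `n_folds` folds so that all images
#' of one lesion land in the same fold, preventing leakage of near-duplicate
#' images between training and validation.  Lesions are shuffled under the
#' seed and dealt round-robin, so fold sizes differ by at most one lesion.
#' Records flagged `train_only` (e.g. external data) are assigned to every
#' training set and no validation set.
#'
#' @param lesion_ids character vector, one entry per image.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the lesion shuffle.
#' @param train_only logical vector per image; `TRUE` marks images that join
#'   all training sets and never a validation set.
#' @return object of class `cv_split`: `fold` (integer per image, `NA` for
#'   train-only images), `n_folds`, `lesion_fold` (named map lesion -> fold).
#' @export
grouped_kfold <- function(lesion_ids, n_folds = 5L, seed = 1L,
                          train_only = rep(FALSE, length(lesion_ids))) {
  abort_if(length(lesion_ids) == 0, "no images supplied")
  abort_if(length(train_only) != length(lesion_ids),
           "train_only must match lesion_ids in length")
  lesions <- unique(lesion_ids[!train_only])
  abort_if(length(lesions) < n_folds,
           sprintf("need at least %d distinct lesions for %d folds",
                   n_folds, n_folds))
  withr::with_seed(seed, {
    shuffled <- sample(lesions)
  })
  lesion_fold <- setNames(rep(seq_len(n_folds), length.out = length(shuffled)),
                          shuffled)
  fold <- unname(lesion_fold[lesion_ids])
  fold[train_only] <- NA_integer_
  structure(list(fold = as.integer(fold), n_folds = as.integer(n_folds),
                 lesion_fold = lesion_fold),
            class = "cv_split")
}

#' Images of the training / validation side of one fold
#'
#' @param split a [grouped_kfold()] result.
#' @param j fold index in `1..n_folds`.
#' @return list with integer index vectors `train` and `val`; train-only
#'   images appear in `train` for every fold.
#' @export
cv_fold_indices <- function(split, j) {
  abort_if(!(j %in% seq_len(split$n_folds)), "fold index out of range")
  val <- which(!is.na(split$fold) & split$fold == j)
  train <- which(is.na(split$fold) | split$fold != j)
  list(train = train, val = val)
}

#' Stage-1 (image-only) training configuration
#'
#' Defaults mirror the published protocol (100 epochs, learning rate halved
#' every 25 epochs, evaluation every 10 epochs, balancing exponent k = 1);
#' epoch counts and the base learning rate are scaled to the backbone, and
#' the shipped tiny backbone uses far fewer epochs in tests.
#'
#' @param epochs training epochs.
#' @param base_lr initial Adam learning rate.
#' @param batch_size minibatch size.
#' @param lr_halving_period epochs between learning-rate halvings.
#' @param eval_period epochs between held-out evaluations.
#' @param k balancing-severity exponent for [class_weights()].
#' @param num_classes number of classes (9 for the full task).
#' @param strategy input strategy: same-sized random crops or random-resize
#'   crops.
#' @param augment an [augment_params()] list.
#' @param seed integer seed controlling shuffling, augmentation and
#'   initialization.
#' @return configuration list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, base_lr = 3e-3, batch_size = 32L,
                         lr_halving_period = 25L, eval_period = 10L, k = 1,
                         num_classes = 9L,
                         strategy = c("same_sized", "random_resize"),
                         augment = augment_params(), seed = 1L) {
  strategy <- match.arg(strategy)
  abort_if(epochs < 1 || batch_size < 1, "epochs and batch_size must be positive")
  abort_if(eval_period < 1 || lr_halving_period < 1, "periods must be positive")
  structure(list(epochs = as.integer(epochs), base_lr = base_lr,
                 batch_size = as.integer(batch_size),
                 lr_halving_period = as.integer(lr_halving_period),
                 eval_period = as.integer(eval_period), k = k,
                 num_classes = as.integer(num_classes), strategy = strategy,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Stage-2 (metadata) training configuration
#'
#' The published protocol trains the metadata layers for 50 epochs with a
#' learning rate of 1e-5 and batch size 20 while the CNN stays frozen; all
#' three are configuration values here because the desk-scale backbone
#' converges with far fewer, larger steps.
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param p_drop metadata-dropout probability (see [apply_meta_dropout()]).
#' @param seed integer seed.
#' @return configuration list of class `meta_train_config`.
#' @export
meta_train_config <- function(epochs = 50L, lr = 1e-5, batch_size = 20L,
                              p_drop = 0.1, seed = 1L) {
  abort_if(epochs < 1 || batch_size < 1, "epochs and batch_size must be positive")
  abort_if(p_drop < 0 || p_drop > 1, "p_drop must be in [0, 1]")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), p_drop = p_drop,
                 cnn_frozen = TRUE, seed = as.integer(seed)),
            class = "meta_train_config")
}

# Per-class weights for one fold's training labels.  Classes absent from
# the fold contribute no loss terms, so their weight is an unused
# placeholder (0); class_weights() keeps its strict all-positive contract
# for direct callers.
fold_class_weights <- function(labels, num_classes, k) {
  cnt <- tabulate(labels + 1L, nbins = num_classes)
  w <- numeric(num_classes)
  if (any(cnt == 0)) {
    present <- cnt > 0
    w[present] <- (sum(cnt) / cnt[present])^k
  } else {
    w <- class_weights(cnt, k = k)$weights
  }
  w
}

# Assemble an (h, w, 3, n) batch from a list of images, applying per-image
# augmentation and the input-cropping strategy.
make_batch <- function(images, input_size, strategy, augment = NULL) {
  n <- length(images)
  x <- array(0, c(input_size[1], input_size[2], 3L, n))
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (!is.null(augment)) im <- random_augment(im, augment)
    im <- switch(strategy,
                 same_sized = same_size_crop(im, input_size),
                 random_resize = random_resize_crop(im, input_size),
                 center = center_crop_view(im, input_size))
    x[, , , i] <- im
  }
  x
}

# Deterministic center view at the network input size (used for held-out
# evaluation during training; full TTA is applied at prediction time).
center_crop_view <- function(img, input_size) {
  img <- pad_to(img, input_size[1], input_size[2])
  h <- dim(img)[1]; w <- dim(img)[2]
  y0 <- (h - input_size[1]) %/% 2L; x0 <- (w - input_size[2]) %/% 2L
  img[y0 + seq_len(input_size[1]), x0 + seq_len(input_size[2]), , drop = FALSE]
}

# Predict class probabilities for a set of images (+ optional metadata) with
# a single deterministic center view per image.
predict_center <- function(model, images, meta_mat = NULL, batch_size = 64L) {
  n <- length(images)
  out <- matrix(0, n, model$num_classes)
  input_size <- model$backbone$input_size
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    x <- make_batch(images[s:e], input_size, "center")
    mm <- if (!is.null(meta_mat)) meta_mat[s:e, , drop = FALSE]
    fw <- model_forward(model, x, mm, train = FALSE)
    out[s:e, ] <- softmax_rows(fw$logits)
  }
  out
}

encode_meta_matrix <- function(meta_records, p_drop = 0) {
  rows <- lapply(meta_records, function(r) {
    if (p_drop > 0) r <- apply_meta_dropout(r, p_drop)
    encode_metadata(r)
  })
  do.call(rbind, rows)
}

# Shared minibatch loop for both stages.
run_training_stage <- function(model, images, labels, meta_records,
                               val_images, val_labels, val_meta,
                               epochs, base_lr, lr_period, eval_period,
                               batch_size, weights, strategy, augment,
                               p_meta_drop = 0, freeze_backbone = FALSE) {
  n <- length(images)
  opt_head <- adam_state(model$params$head)
  opt_bb <- if (!freeze_backbone) adam_state(model$params$backbone)
  input_size <- model$backbone$input_size
  history <- data.frame(epoch = integer(0), loss = numeric(0), S = numeric(0))
  best <- NULL

  eval_S <- function() {
    vm <- if (model$mode == "meta") encode_meta_matrix(val_meta) else NULL
    probs <- predict_center(model, val_images, vm)
    suppressWarnings(mean_sensitivity(val_labels, probs, C_cls = model$num_classes))
  }

  for (epoch in 0:(epochs - 1L)) {
    lr <- lr_schedule(epoch, base_lr, lr_period)
    ord <- sample(n)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(n, s + batch_size - 1L)]
      x <- make_batch(images[idx], input_size, strategy, augment)
      mm <- if (model$mode == "meta")
        encode_meta_matrix(meta_records[idx], p_meta_drop)
      fw <- model_forward(model, x, mm, train = TRUE)
      model <- fw$model
      ce <- weighted_cross_entropy(fw$logits, labels[idx], weights)
      abort_if(!is.finite(ce$loss), "training diverged: non-finite loss")
      gr <- model_backward(model, fw$cache, ce$dlogits, freeze_backbone)
      sh <- adam_step(model$params$head, gr$head, opt_head, lr)
      model$params$head <- sh$params; opt_head <- sh$state
      if (!freeze_backbone) {
        sb <- adam_step(model$params$backbone, gr$backbone, opt_bb, lr)
        model$params$backbone <- sb$params; opt_bb <- sb$state
      }
      ep_loss <- ep_loss + ce$loss; nb <- nb + 1L
    }
    at_eval <- (epoch + 1L) %% eval_period == 0L || epoch == epochs - 1L
    if (at_eval && length(val_images) > 0) {
      S <- eval_S()
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / nb, S = S))
      # strict > keeps the earlier epoch on ties (less overfit)
      if (is.null(best) || S > best$S)
        best <- list(kind = "best", epoch = epoch, params = model$params,
                     bn_state = model$bn_state, S = S)
    }
  }
  last_S <- if (nrow(history) > 0) history$S[nrow(history)] else NA_real_
  last <- list(kind = "last", epoch = epochs - 1L, params = model$params,
               bn_state = model$bn_state, S = last_S)
  if (is.null(best))
    best <- list(kind = "best", epoch = last$epoch, params = last$params,
                 bn_state = last$bn_state, S = last$S)
  list(best = best, last = last, history = history, model = model)
}

checkpoint_model <- function(model, ckpt) {
  model$params <- ckpt$params
  if (!is.null(ckpt$bn_state) && length(ckpt$bn_state)) model$bn_state <- ckpt$bn_state
  model
}

#' Stage-1 training: image-only CNN per cross-validation fold
#'
#' For each requested fold, trains an image-only model on the fold's training
#' images with weighted cross-entropy, augmentation and the configured input
#' strategy, evaluates mean sensitivity on the held-out images every
#' `eval_period` epochs, and records both the best-so-far and the final
#' checkpoint.
#'
#' @param dataset a `lesion_dataset` whose records are preprocessed.
#' @param split a [grouped_kfold()] over the dataset's lesion ids.
#' @param config a [train_config()].
#' @param backbone backbone object (default [tiny_backbone()]).
#' @param folds which folds to train (default all).
#' @return list of class `fold_checkpoints`: per fold, `best`, `last`
#'   (parameter snapshots with achieved S) and the evaluation `history`.
#' @export
train_cnn <- function(dataset, split, config = train_config(),
                      backbone = tiny_backbone(), folds = seq_len(split$n_folds)) {
  images <- lapply(dataset$records, `[[`, "image")
  labels <- dataset$labels
  weights <- NULL
  out <- list()
  withr::with_seed(config$seed, {
    for (j in folds) {
      fi <- cv_fold_indices(split, j)
      weights <- fold_class_weights(labels[fi$train], config$num_classes, config$k)
      model <- build_two_branch_model(backbone, mode = "image_only",
                                      num_classes = config$num_classes,
                                      seed = sample.int(2^31 - 1, 1))
      st <- run_training_stage(model, images[fi$train], labels[fi$train], NULL,
                               images[fi$val], labels[fi$val], NULL,
                               epochs = config$epochs, base_lr = config$base_lr,
                               lr_period = config$lr_halving_period,
                               eval_period = config$eval_period,
                               batch_size = config$batch_size,
                               weights = weights, strategy = config$strategy,
                               augment = config$augment)
      out[[as.character(j)]] <- list(best = st$best, last = st$last,
                                     history = st$history)
    }
  })
  structure(list(folds = out, config = config, backbone = backbone,
                 mode = "image_only"),
            class = "fold_checkpoints")
}

#' Stage-2 training: metadata branch on top of a frozen CNN
#'
#' Rebuilds each fold's model in `"meta"` mode around the stage-1 backbone
#' weights, then trains only the metadata branch, fusion layer and
#' classifier (the backbone parameters are bit-identical before and after).
#' Image augmentation remains active, so the frozen CNN still produces
#' varying features per epoch; metadata properties are randomly masked with
#' probability `p_drop`.
#'
#' @param dataset a `lesion_dataset` with metadata.
#' @param split the same [grouped_kfold()] used for stage 1.
#' @param stage1 a `fold_checkpoints` from [train_cnn()].
#' @param config a [meta_train_config()].
#' @param meta_spec a [meta_branch_spec()].
#' @param use stage-1 checkpoint to freeze: `"best"` or `"last"`.
#' @return a `fold_checkpoints` in meta mode.
#' @export
train_meta <- function(dataset, split, stage1, config = meta_train_config(),
                       meta_spec = meta_branch_spec(), use = "best") {
  abort_if(!inherits(stage1, "fold_checkpoints"), "stage1 must come from train_cnn")
  images <- lapply(dataset$records, `[[`, "image")
  labels <- dataset$labels
  meta_records <- read_isic_metadata(dataset$meta)
  backbone <- stage1$backbone
  s1cfg <- stage1$config
  out <- list()
  withr::with_seed(config$seed, {
    for (j in names(stage1$folds)) {
      ji <- as.integer(j)
      fi <- cv_fold_indices(split, ji)
      ck <- stage1$folds[[j]][[use]]
      abort_if(is.null(ck), sprintf("missing stage-1 '%s' checkpoint for fold %s", use, j))
      weights <- fold_class_weights(labels[fi$train], s1cfg$num_classes, s1cfg$k)
      model <- build_two_branch_model(backbone, meta_spec, mode = "meta",
                                      num_classes = s1cfg$num_classes,
                                      seed = sample.int(2^31 - 1, 1))
      model$params$backbone <- ck$params$backbone   # frozen from stage 1
      st <- run_training_stage(model, images[fi$train], labels[fi$train],
                               meta_records[fi$train],
                               images[fi$val], labels[fi$val],
                               meta_records[fi$val],
                               epochs = config$epochs, base_lr = config$lr,
                               lr_period = .Machine$integer.max,
                               eval_period = max(1L, config$epochs %/% 5L),
                               batch_size = config$batch_size,
                               weights = weights, strategy = s1cfg$strategy,
                               augment = s1cfg$augment,
                               p_meta_drop = config$p_drop,
                               freeze_backbone = TRUE)
      stopifnot(identical(st$best$params$backbone, ck$params$backbone))
      out[[j]] <- list(best = st$best, last = st$last, history = st$history)
    }
  })
  structure(list(folds = out, config = config, backbone = backbone,
                 mode = "meta", meta_spec = meta_spec),
            class = "fold_checkpoints")
}

#' Rebuild a model from a fold checkpoint
#'
#' @param ckpts a `fold_checkpoints` object.
#' @param fold fold id (character or integer).
#' @param use `"best"` or `"last"`.
#' @return a `dermpipe_model` carrying the checkpoint's parameters.
#' @export
model_from_checkpoint <- function(ckpts, fold, use = "best") {
  ck <- ckpts$folds[[as.character(fold)]][[use]]
  abort_if(is.null(ck), "no such checkpoint")
  ncl <- length(ck$params$head$classifier$b)
  if (ckpts$mode == "meta") {
    model <- build_two_branch_model(ckpts$backbone, ckpts$meta_spec,
                                    mode = "meta", num_classes = ncl)
  } else {
    model <- build_two_branch_model(ckpts$backbone, mode = "image_only",
                                    num_classes = ncl)
  }
  checkpoint_model(model, ck)
}
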