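# Synthetic dermoscopy fixtures.
#
# Every downstream stage (preprocessing, training, TTA, ensembling) is
# exercised on data generated here: circular fields of view inside noisy
# near-black borders, lesion-like elliptical blobs whose hue and size depend
# on the class index, lesion-grouped datasets with partially missing
# metadata, and per-configuration/per-fold class-probability tensors of
# controllable skill.  The generator does not attempt photorealism (no hair,
# rulers, or gel artifacts); it provides exact ground truth instead.

#' ISIC 2019 class labels
#'
#' The nine diagnostic categories: melanoma, melanocytic nevus, basal cell
#' carcinoma, actinic keratosis, benign keratosis, dermatofibroma, vascular
#' lesion, squamous cell carcinoma, and the unknown catch-all class.
#'
#' @return character vector of length 9.
#' @export
isic_classes <- function() {
  c("MEL", "NV", "BCC", "AK", "BKL", "DF", "VASC", "SCC", "UNK")
}

#' Specification of one synthetic dermoscopy image
#'
#' @param width,height image size in pixels.
#' @param fov_center `c(x, y)` center of the field-of-view disk, 0-based
#'   pixel coordinates; defaults to the image center.
#' @param fov_radius disk radius in pixels; 0 means a full-frame image with
#'   no black border.  When nonzero it must not exceed `min(width, height)/2`.
#' @param lesion_class integer class index in 0..8.
#' @param image_class_signal when `FALSE` the lesion's appearance is
#'   identical for all classes, so the image carries no class information
#'   (used to probe metadata-only learning).
#' @param seed integer seed; identical spec + seed reproduces the image
#'   bit for bit.
#' @return a validated spec list of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(width, height,
                                 fov_center = c(width / 2, height / 2),
                                 fov_radius = 0, lesion_class = 0L,
                                 image_class_signal = TRUE, seed = 1L) {
  abort_if(width < 8 || height < 8, "image dimensions must be at least 8 pixels")
  abort_if(fov_radius < 0, "fov_radius must be non-negative")
  abort_if(fov_radius > 0 && fov_radius > min(width, height) / 2,
           "fov_radius must be at most min(width, height)/2")
  abort_if(!(lesion_class %in% 0:8), "lesion_class must be an integer in 0..8")
  structure(list(width = as.integer(width), height = as.integer(height),
                 fov_center = as.numeric(fov_center),
                 fov_radius = as.numeric(fov_radius),
                 lesion_class = as.integer(lesion_class),
                 image_class_signal = isTRUE(image_class_signal),
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Class-dependent lesion appearance: hue and relative size vary
# deterministically with the class index so a small CNN can separate the
# nine classes from color and extent alone.
lesion_appearance <- function(class_idx) {
  hue <- class_idx / 9
  list(col = grDevices::hsv(h = hue, s = 0.65, v = 0.45),
       rel_size = 0.25 + 0.04 * class_idx)
}

#' Generate one synthetic dermoscopy image
#'
#' Renders a skin-toned disk (the field of view) over a noisy near-black
#' border (uniform intensity in \[0, 10\]/255, mimicking sensor noise), with
#' an elliptical lesion blob near the disk center whose hue and size are a
#' deterministic function of the class.  With `fov_radius = 0` the skin fills
#' the whole frame.
#'
#' @param spec a [synthetic_image_spec()].
#' @return list with `record` (an [image_record()]) and `gt_box` (the exact
#'   [fov_box()] circumscribing the FOV disk; the full frame when
#'   `fov_radius = 0`).
#' @export
gen_dermoscopy_image <- function(spec) {
  abort_if(!inherits(spec, "synthetic_image_spec"), "spec must be a synthetic_image_spec")
  withr::with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    cx <- spec$fov_center[1]; cy <- spec$fov_center[2]
    r <- spec$fov_radius
    xg <- matrix(rep(0:(w - 1), each = h), h, w)
    yg <- matrix(rep(0:(h - 1), times = w), h, w)

    img <- array(runif(h * w * 3, 0, 10 / 255), c(h, w, 3))  # border noise
    fov <- if (r > 0) (xg - cx)^2 + (yg - cy)^2 <= r^2 else matrix(TRUE, h, w)

    skin <- c(0.80, 0.62, 0.55)
    for (c in 1:3) {
      layer <- img[, , c]
      layer[fov] <- clip01(skin[c] + rnorm(sum(fov), 0, 0.02))
      img[, , c] <- layer
    }

    app <- lesion_appearance(if (spec$image_class_signal) spec$lesion_class else 4L)
    lcol <- as.vector(grDevices::col2rgb(app$col)) / 255
    extent <- if (r > 0) r else min(w, h) / 2
    la <- app$rel_size * extent
    lb <- la * runif(1, 0.6, 0.95)
    lth <- runif(1, -pi / 2, pi / 2)
    lcx <- cx + runif(1, -0.15, 0.15) * extent
    lcy <- cy + runif(1, -0.15, 0.15) * extent
    xr <- (xg - lcx) * cos(lth) + (yg - lcy) * sin(lth)
    yr <- -(xg - lcx) * sin(lth) + (yg - lcy) * cos(lth)
    lesion <- ((xr / la)^2 + (yr / lb)^2 <= 1) & fov
    for (c in 1:3) {
      layer <- img[, , c]
      layer[lesion] <- clip01(lcol[c] + rnorm(sum(lesion), 0, 0.02))
      img[, , c] <- layer
    }

    gt <- if (r > 0)
      fov_box(max(0, floor(cx - r)), max(0, floor(cy - r)),
              min(w, ceiling(cx + r)), min(h, ceiling(cy + r)))
    else fov_box(0, 0, w, h)

    rec <- image_record(img, image_id = sprintf("SYN_%08d", spec$seed),
                        label = spec$lesion_class)
    list(record = rec, gt_box = gt)
  })
}

#' Specification of a synthetic lesion-grouped dataset
#'
#' @param n_lesions number of distinct lesions (> 0).
#' @param images_per_lesion a single count or a `c(min, max)` range; every
#'   image of a lesion shares its class label.
#' @param class_probabilities probability of each of the 9 classes; must sum
#'   to 1 within 1e-9.
#' @param metadata_missing_rates named or unnamed length-3 vector of
#'   per-property missingness probabilities for (age, site, sex).
#' @param image_size `c(width, height)` of generated images.
#' @param fov_radius_range `c(min, max)` FOV radius as a fraction of
#'   `min(width, height)/2`; use `c(0, 0)` for full-frame images.
#' @param image_class_signal,metadata_class_signal control where class
#'   information lives: in the lesion appearance, in the metadata
#'   (site = class mod 8, age = 10 * class), in both, or in neither.
#' @param seed integer seed.
#' @return a validated spec list of class `synthetic_dataset_spec`.
#' @export
synthetic_dataset_spec <- function(n_lesions, images_per_lesion = 1L,
                                   class_probabilities = rep(1 / 9, 9),
                                   metadata_missing_rates = c(age = 0, site = 0, sex = 0),
                                   image_size = c(96L, 96L),
                                   fov_radius_range = c(0.8, 0.95),
                                   image_class_signal = TRUE,
                                   metadata_class_signal = FALSE,
                                   seed = 1L) {
  abort_if(n_lesions < 1, "n_lesions must be positive")
  abort_if(length(class_probabilities) != 9, "class_probabilities must have length 9")
  abort_if(abs(sum(class_probabilities) - 1) > 1e-9,
           "class_probabilities must sum to 1 within 1e-9")
  abort_if(any(class_probabilities < 0), "class_probabilities must be non-negative")
  abort_if(length(metadata_missing_rates) != 3 ||
             any(metadata_missing_rates < 0 | metadata_missing_rates > 1),
           "metadata_missing_rates must be 3 probabilities in [0, 1]")
  ipl <- as.integer(images_per_lesion)
  abort_if(any(ipl < 1), "images_per_lesion must be >= 1")
  if (length(ipl) == 1L) ipl <- c(ipl, ipl)
  structure(list(n_lesions = as.integer(n_lesions), images_per_lesion = ipl,
                 class_probabilities = as.numeric(class_probabilities),
                 metadata_missing_rates = setNames(as.numeric(metadata_missing_rates),
                                                   c("age", "site", "sex")),
                 image_size = as.integer(image_size),
                 fov_radius_range = as.numeric(fov_radius_range),
                 image_class_signal = isTRUE(image_class_signal),
                 metadata_class_signal = isTRUE(metadata_class_signal),
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Generate a lesion-grouped synthetic dataset
#'
#' Draws a class per lesion, renders 1 or more images per lesion (all sharing
#' the lesion's label), and attaches patient metadata with fields missing
#' independently at the configured rates.  Ages are multiples of five years
#' in 0..85, mirroring ISIC's five-year age groups.
#'
#' @param spec a [synthetic_dataset_spec()].
#' @return list of class `lesion_dataset` with elements `records` (list of
#'   [image_record()]), `labels` (integer 0..8 per image), `lesion_ids`,
#'   `meta` (data.frame: image, age_approx, anatom_site_general, sex, with
#'   `NA` for missing), and `gt_boxes`.
#' @export
gen_lesion_dataset <- function(spec) {
  abort_if(!inherits(spec, "synthetic_dataset_spec"), "spec must be a synthetic_dataset_spec")
  withr::with_seed(spec$seed, {
    nl <- spec$n_lesions
    lesion_class <- sample(0:8, nl, replace = TRUE, prob = spec$class_probabilities)
    ipl_range <- spec$images_per_lesion[1]:spec$images_per_lesion[2]
    n_img <- ipl_range[sample.int(length(ipl_range), nl, replace = TRUE)]
    sites <- isic_sites()

    records <- list(); labels <- integer(0); lesion_ids <- character(0)
    gt_boxes <- list()
    meta_rows <- list()
    img_seeds <- sample.int(.Machine$integer.max, sum(n_img))
    k <- 0L
    for (l in seq_len(nl)) {
      lid <- sprintf("LES_%06d", l)
      # one patient per lesion: metadata constant across its images
      if (spec$metadata_class_signal) {
        age <- 10L * lesion_class[l]
        site <- sites[(lesion_class[l] %% 8L) + 1L]
        sex <- c("female", "male")[(lesion_class[l] %% 2L) + 1L]
      } else {
        age <- 5L * sample(0:17, 1)
        site <- sample(sites, 1)
        sex <- sample(c("female", "male"), 1)
      }
      for (i in seq_len(n_img[l])) {
        k <- k + 1L
        w <- spec$image_size[1]; h <- spec$image_size[2]
        rr <- spec$fov_radius_range
        rad <- if (rr[2] > 0) runif(1, rr[1], rr[2]) * min(w, h) / 2 else 0
        ctr <- c(w / 2, h / 2)
        if (rad > 0) {  # jitter center while keeping the disk inside the frame
          ctr <- ctr + c(runif(1, -1, 1) * (w / 2 - rad),
                         runif(1, -1, 1) * (h / 2 - rad))
        }
        ispec <- synthetic_image_spec(w, h, fov_center = ctr, fov_radius = rad,
                                      lesion_class = lesion_class[l],
                                      image_class_signal = spec$image_class_signal,
                                      seed = img_seeds[k])
        gen <- gen_dermoscopy_image(ispec)
        rec <- gen$record
        rec$image_id <- sprintf("ISIC_SYN_%07d", k)
        rec$lesion_id <- lid
        records[[k]] <- rec
        labels[k] <- lesion_class[l]
        lesion_ids[k] <- lid
        gt_boxes[[k]] <- gen$gt_box
        mr <- spec$metadata_missing_rates
        meta_rows[[k]] <- data.frame(
          image = rec$image_id,
          age_approx = if (runif(1) < mr["age"]) NA_integer_ else age,
          anatom_site_general = if (runif(1) < mr["site"]) NA_character_ else site,
          sex = if (runif(1) < mr["sex"]) NA_character_ else sex,
          stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, meta_rows)
    structure(list(records = records, labels = labels, lesion_ids = lesion_ids,
                   meta = meta, gt_boxes = gt_boxes),
              class = "lesion_dataset")
  })
}

#' @export
print.lesion_dataset <- function(x, ...) {
  cat(sprintf("<lesion_dataset  %d images, %d lesions, %d classes present>\n",
              length(x$records), length(unique(x$lesion_ids)),
              length(unique(x$labels))))
  invisible(x)
}

#' Specification of a synthetic prediction tensor
#'
#' @param n_configs number of model configurations.
#' @param n_folds number of cross-validation folds (default 5).
#' @param n_images_per_fold held-out images per fold.
#' @param n_classes number of classes (>= 2).
#' @param skill scalar in \[0, 1\], or a vector of length `n_configs`,
#'   controlling how concentrated each configuration's probabilities are on
#'   the true class: 0 gives exchangeable chance-level rows, 1 puts the
#'   argmax on the true label for every row.
#' @param seed integer seed.
#' @return a validated spec list of class `synthetic_prediction_spec`.
#' @export
synthetic_prediction_spec <- function(n_configs, n_folds = 5L,
                                      n_images_per_fold = 100L, n_classes = 9L,
                                      skill = 0.5, seed = 1L) {
  abort_if(n_configs < 1, "n_configs must be positive")
  abort_if(n_folds < 1, "n_folds must be positive")
  abort_if(n_images_per_fold < 1, "n_images_per_fold must be positive")
  abort_if(n_classes < 2, "n_classes must be at least 2")
  abort_if(any(skill < 0 | skill > 1), "skill must be in [0, 1]")
  abort_if(!(length(skill) %in% c(1L, n_configs)),
           "skill must be scalar or one value per configuration")
  if (length(skill) == 1L) skill <- rep(skill, n_configs)
  structure(list(n_configs = as.integer(n_configs), n_folds = as.integer(n_folds),
                 n_images_per_fold = as.integer(n_images_per_fold),
                 n_classes = as.integer(n_classes), skill = as.numeric(skill),
                 seed = as.integer(seed)),
            class = "synthetic_prediction_spec")
}

#' Generate a synthetic per-configuration, per-fold prediction tensor
#'
#' Each cell holds an `n_images_per_fold x n_classes` row-stochastic matrix.
#' Rows are Dirichlet(1) draws blended with the true-label one-hot vector by
#' the configuration's skill: at skill 0 rows are exchangeable across
#' classes (chance level), at skill 1 the argmax equals the true label for
#' every row.  True labels are shared across configurations within a fold,
#' as they would be for real cross-validation predictions.
#'
#' @param spec a [synthetic_prediction_spec()].
#' @return a `prediction_tensor` (see [prediction_tensor()]).
#' @export
gen_prediction_tensor <- function(spec) {
  abort_if(!inherits(spec, "synthetic_prediction_spec"),
           "spec must be a synthetic_prediction_spec")
  withr::with_seed(spec$seed, {
    K <- spec$n_classes
    labels <- lapply(seq_len(spec$n_folds), function(j)
      sample(0:(K - 1), spec$n_images_per_fold, replace = TRUE))
    preds <- lapply(seq_len(spec$n_configs), function(i) {
      lapply(seq_len(spec$n_folds), function(j) {
        n <- spec$n_images_per_fold
        g <- matrix(stats::rexp(n * K), n, K)       # Dirichlet(1) rows
        p <- g / rowSums(g)
        onehot <- matrix(0, n, K)
        onehot[cbind(seq_len(n), labels[[j]] + 1L)] <- 1
        s <- spec$skill[i]
        # blend weight > 1/2 guarantees argmax = truth at skill 1
        w <- s * (0.5 + 0.5 * s)
        q <- (1 - w) * p + w * onehot
        q / rowSums(q)
      })
    })
    prediction_tensor(preds, labels)
  })
}

#' Write a lesion dataset to disk in ISIC layout
#'
#' Writes one PNG per image plus `metadata.csv` (image, age_approx,
#' anatom_site_general, sex; empty cells for missing values) and
#' `groundtruth.csv` (image + nine one-hot class columns), the layout used by
#' the ISIC 2019 challenge.
#'
#' @param ds a `lesion_dataset` from [gen_lesion_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lesion_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  for (rec in ds$records)
    write_image_png(rec$image, file.path(img_dir, paste0(rec$image_id, ".png")))
  meta <- ds$meta
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE, na = "")
  gt <- data.frame(image = vapply(ds$records, `[[`, "", "image_id"))
  onehot <- matrix(0, nrow(gt), 9, dimnames = list(NULL, isic_classes()))
  onehot[cbind(seq_len(nrow(gt)), ds$labels + 1L)] <- 1
  gt <- cbind(gt, as.data.frame(onehot))
  write.csv(gt, file.path(dir, "groundtruth.csv"), row.names = FALSE)
  lid <- data.frame(image = gt$image, lesion_id = ds$lesion_ids)
  write.csv(lid, file.path(dir, "lesions.csv"), row.names = FALSE)
  invisible(dir)
}
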