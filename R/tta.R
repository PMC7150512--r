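# Deterministic multi-view test-time augmentation.
#
# Predictions average softmax outputs over a fixed view set: 36 ordered
# crops (a 6x6 grid) for the same-sized strategy, or 16 views (4 scaled
# center crops x 4 flip variants) for the random-resize strategy.  Metadata,
# when present, is passed unchanged with every view.

#' 36 ordered crops on a 6x6 grid
#'
#' Top-left corners are evenly spaced from 0 to `dim - crop` along each axis
#' (so the four image corners and the center are covered); images smaller
#' than the crop are zero-padded first.  Fully deterministic.
#'
#' @param img RGB array.
#' @param crop_size `c(h, w)` or a single side length.
#' @return list of class `view_set`: `views` (36 arrays of `crop_size`),
#'   `strategy`, and per-view `provenance` (grid positions).
#' @export
ordered_crops <- function(img, crop_size) {
  check_image(img)
  if (length(crop_size) == 1L) crop_size <- c(crop_size, crop_size)
  img <- pad_to(img, crop_size[1], crop_size[2])
  h <- dim(img)[1]; w <- dim(img)[2]
  ys <- as.integer(round(seq(0, h - crop_size[1], length.out = 6)))
  xs <- as.integer(round(seq(0, w - crop_size[2], length.out = 6)))
  views <- vector("list", 36L)
  prov <- vector("list", 36L)
  k <- 0L
  for (gy in 1:6) for (gx in 1:6) {
    k <- k + 1L
    views[[k]] <- img[ys[gy] + seq_len(crop_size[1]),
                      xs[gx] + seq_len(crop_size[2]), , drop = FALSE]
    prov[[k]] <- c(grid_y = gy, grid_x = gx, y0 = ys[gy], x0 = xs[gx])
  }
  structure(list(views = views, strategy = "same_sized", provenance = prov),
            class = "view_set")
}

#' 16 evaluation views: 4 scaled center crops x 4 flips
#'
#' Center crops at fractions `scales` of the shorter image side, each resized
#' to `crop_size` and expanded into its identity, horizontal, vertical and
#' double-flip variants: 4 x 4 = 16 deterministic views.
#'
#' @param img RGB array.
#' @param crop_size `c(h, w)` or a single side length.
#' @param scales four center-crop fractions of the shorter side.
#' @return a `view_set` of 16 views.
#' @export
rr_eval_views <- function(img, crop_size, scales = c(1, 0.875, 0.75, 0.625)) {
  check_image(img)
  abort_if(length(scales) != 4, "exactly four scales expected")
  abort_if(any(scales <= 0 | scales > 1), "scales must be in (0, 1]")
  if (length(crop_size) == 1L) crop_size <- c(crop_size, crop_size)
  h <- dim(img)[1]; w <- dim(img)[2]
  s0 <- min(h, w)
  views <- list(); prov <- list()
  for (sc in scales) {
    s <- max(1L, as.integer(round(sc * s0)))
    y0 <- (h - s) %/% 2L; x0 <- (w - s) %/% 2L
    win <- img[y0 + seq_len(s), x0 + seq_len(s), , drop = FALSE]
    base <- resize_to(win, crop_size[1], crop_size[2])
    for (fl in c("identity", "h", "v", "hv")) {
      v <- switch(fl, identity = base, h = flip_h(base), v = flip_v(base),
                  hv = flip_v(flip_h(base)))
      views[[length(views) + 1L]] <- v
      prov[[length(prov) + 1L]] <- c(scale = sc, flip = fl)
    }
  }
  structure(list(views = views, strategy = "random_resize", provenance = prov),
            class = "view_set")
}

#' Multi-view averaged prediction for one image
#'
#' Runs every view of the strategy's view set through the model (in
#' evaluation mode) together with the unchanged metadata vector, softmaxes
#' each view's logits and returns their arithmetic mean — a valid
#' probability vector.
#'
#' @param model a `dermpipe_model`.
#' @param img preprocessed RGB array.
#' @param meta encoded 11-dimensional metadata vector
#'   (see [encode_metadata()]), or `NULL` for an image-only model.
#' @param strategy `"same_sized"` (36 ordered crops) or `"random_resize"`
#'   (16 scaled/flipped views).
#' @return list of class `averaged_prediction`: `probs` (length-`C` vector
#'   summing to 1) and `per_view` (view x class matrix, kept for audit).
#' @export
tta_predict <- function(model, img, meta = NULL,
                        strategy = c("same_sized", "random_resize")) {
  strategy <- match.arg(strategy)
  if (model$mode == "image_only")
    abort_if(!is.null(meta), "metadata supplied to an image-only model")
  else abort_if(is.null(meta), "meta-mode model requires a metadata vector")
  vs <- switch(strategy,
               same_sized = ordered_crops(img, model$backbone$input_size),
               random_resize = rr_eval_views(img, model$backbone$input_size))
  nv <- length(vs$views)
  x <- array(0, c(model$backbone$input_size, 3L, nv))
  for (i in seq_len(nv)) x[, , , i] <- vs$views[[i]]
  mm <- if (!is.null(meta)) matrix(rep(meta, each = nv), nv, length(meta))
  fw <- model_forward(model, x, mm, train = FALSE)
  per_view <- softmax_rows(fw$logits)
  structure(list(probs = colMeans(per_view), per_view = per_view),
            class = "averaged_prediction")
}

#' Write predictions in the ISIC challenge submission format
#'
#' CSV with header `image,MEL,NV,BCC,AK,BKL,DF,VASC,SCC,UNK`; one
#' probability row per image.
#'
#' @param probs matrix with one row per image and 9 columns, or a named list
#'   of length-9 vectors.
#' @param image_ids character ids, one per row (ignored when `probs` is a
#'   named list).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(probs, image_ids, path) {
  if (is.list(probs) && !is.data.frame(probs)) {
    image_ids <- names(probs)
    probs <- do.call(rbind, probs)
  }
  abort_if(ncol(probs) != 9, "nine class columns required")
  abort_if(length(image_ids) != nrow(probs), "one id per prediction row")
  abort_if(anyDuplicated(image_ids) > 0, "duplicate image ids in submission")
  df <- data.frame(image = image_ids, probs)
  names(df) <- c("image", isic_classes())
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a submission CSV back into a probability matrix
#'
#' @param path CSV written by [write_submission()].
#' @return matrix with image ids as rownames and the 9 classes as columns.
#' @export
read_submission <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  abort_if(!identical(names(df), c("image", isic_classes())),
           "not a submission CSV")
  m <- as.matrix(df[, -1])
  rownames(m) <- df$image
  m
}
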