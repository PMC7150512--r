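# Training-time image augmentation: photometric jitter, flips, affine
# geometric transforms, CutOut occlusion, and the two input-cropping
# strategies (same-sized random crops vs ImageNet-style random-resize crops).
# All sampling uses the current R RNG state, so pipelines are reproducible
# bit for bit under a fixed seed.

#' Augmentation parameters
#'
#' The transform families are fixed (brightness, contrast, flips, rotation,
#' isotropic scale, shear, CutOut); their magnitudes are configuration
#' values.
#'
#' @param brightness_range additive brightness delta range on the \[0, 1\]
#'   intensity scale.
#' @param contrast_range multiplicative contrast factor range around 1.
#' @param rotation_range rotation angle range in degrees.
#' @param scale_range isotropic scale factor range.
#' @param shear_range shear angle range in degrees.
#' @param hflip_prob,vflip_prob flip probabilities.
#' @param cutout_holes number of CutOut holes (default 1).
#' @param cutout_size CutOut hole side length in pixels (default 16).
#' @return parameter list of class `augment_params`.
#' @export
augment_params <- function(brightness_range = c(-0.3, 0.3),
                           contrast_range = c(0.7, 1.3),
                           rotation_range = c(-180, 180),
                           scale_range = c(0.8, 1.2),
                           shear_range = c(-10, 10),
                           hflip_prob = 0.5, vflip_prob = 0.5,
                           cutout_holes = 1L, cutout_size = 16L) {
  chk_range <- function(r, nm) abort_if(length(r) != 2 || r[1] > r[2],
                                        paste(nm, "must be an ordered range"))
  chk_range(brightness_range, "brightness_range")
  chk_range(contrast_range, "contrast_range")
  chk_range(rotation_range, "rotation_range")
  chk_range(scale_range, "scale_range")
  chk_range(shear_range, "shear_range")
  abort_if(cutout_holes < 0, "cutout_holes must be >= 0")
  abort_if(cutout_holes > 0 && cutout_size <= 0, "cutout_size must be positive")
  structure(list(brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 rotation_range = rotation_range,
                 scale_range = scale_range, shear_range = shear_range,
                 hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 cutout_holes = as.integer(cutout_holes),
                 cutout_size = as.integer(cutout_size)),
            class = "augment_params")
}

flip_h <- function(img) img[, dim(img)[2]:1, , drop = FALSE]
flip_v <- function(img) img[dim(img)[1]:1, , , drop = FALSE]

#' CutOut occlusion
#'
#' Zeroes `holes` square regions of side `size`, each centered at a pixel
#' drawn uniformly over the image; regions are clipped at the borders (a
#' hole centered in a corner removes only its visible quadrant).
#'
#' @param img RGB array.
#' @param holes number of holes.
#' @param size hole side length in pixels; must not exceed either image side.
#' @return augmented RGB array.
#' @export
cutout <- function(img, holes = 1L, size = 16L) {
  check_image(img)
  if (holes < 1L) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  abort_if(size > min(h, w), "cutout size must not exceed the image sides")
  half <- size %/% 2L
  for (k in seq_len(holes)) {
    cy <- sample.int(h, 1) - 1L; cx <- sample.int(w, 1) - 1L
    y0 <- max(0L, cy - half); y1 <- min(h, cy + half)
    x0 <- max(0L, cx - half); x1 <- min(w, cx + half)
    if (y1 > y0 && x1 > x0) img[(y0 + 1L):y1, (x0 + 1L):x1, ] <- 0
  }
  img
}

#' Apply one random draw of the composed augmentation
#'
#' Order: affine (rotation + scale + shear about the image center, black
#' fill), flips, brightness/contrast, CutOut.  The sampled magnitudes are
#' attached as the `"augment_draw"` attribute for auditability.
#'
#' @param img RGB array.
#' @param params an [augment_params()] list.
#' @return augmented RGB array with an `"augment_draw"` attribute.
#' @export
random_augment <- function(img, params = augment_params()) {
  check_image(img)
  draw <- list(
    angle = runif(1, params$rotation_range[1], params$rotation_range[2]),
    scale = runif(1, params$scale_range[1], params$scale_range[2]),
    shear = runif(1, params$shear_range[1], params$shear_range[2]),
    hflip = runif(1) < params$hflip_prob,
    vflip = runif(1) < params$vflip_prob,
    brightness = runif(1, params$brightness_range[1], params$brightness_range[2]),
    contrast = runif(1, params$contrast_range[1], params$contrast_range[2]))
  out <- img
  if (draw$angle != 0 || draw$scale != 1 || draw$shear != 0) {
    Tm <- make_affine(dim(img)[2], dim(img)[1],
                      angle_deg = draw$angle, scale = draw$scale,
                      shear_deg = draw$shear)
    out <- affine_warp(out, Tm)
  }
  if (draw$hflip) out <- flip_h(out)
  if (draw$vflip) out <- flip_v(out)
  if (draw$contrast != 1) out <- (out - 0.5) * draw$contrast + 0.5
  if (draw$brightness != 0) out <- out + draw$brightness
  out <- clip01(out)
  if (params$cutout_holes > 0)
    out <- cutout(out, params$cutout_holes, params$cutout_size)
  attr(out, "augment_draw") <- draw
  out
}

#' Same-sized random crop
#'
#' Takes a `crop_size` window at an offset uniform over all valid positions;
#' images smaller than the crop are first zero-padded to the crop size
#' (content centered).
#'
#' @param img RGB array.
#' @param crop_size `c(h, w)` or a single side length.
#' @return cropped RGB array of exactly `crop_size`.
#' @export
same_size_crop <- function(img, crop_size) {
  check_image(img)
  if (length(crop_size) == 1L) crop_size <- c(crop_size, crop_size)
  img <- pad_to(img, crop_size[1], crop_size[2])
  h <- dim(img)[1]; w <- dim(img)[2]
  y0 <- sample.int(h - crop_size[1] + 1L, 1) - 1L
  x0 <- sample.int(w - crop_size[2] + 1L, 1) - 1L
  out <- img[y0 + seq_len(crop_size[1]), x0 + seq_len(crop_size[2]), , drop = FALSE]
  attr(out, "crop_offset") <- c(x = x0, y = y0)
  out
}

#' ImageNet-style random-resize crop
#'
#' Samples a target area fraction uniformly in `scale_range` and an aspect
#' ratio log-uniformly in `aspect_range`, crops a window with those
#' dimensions at a uniform position, and resizes it to `crop_size`.  If no
#' feasible window is found within 10 attempts, falls back to a center crop
#' of the shorter side.
#'
#' @param img RGB array.
#' @param crop_size `c(h, w)` or a single side length.
#' @param scale_range area-fraction range (default the ImageNet convention
#'   `c(0.08, 1)`).
#' @param aspect_range aspect-ratio (w/h) range (default `c(3/4, 4/3)`).
#' @return RGB array of exactly `crop_size`, with the sampled area fraction
#'   in the `"rr_draw"` attribute (NA for the fallback).
#' @export
random_resize_crop <- function(img, crop_size, scale_range = c(0.08, 1),
                               aspect_range = c(3 / 4, 4 / 3)) {
  check_image(img)
  abort_if(scale_range[1] <= 0 || scale_range[1] > scale_range[2] || scale_range[2] > 1,
           "scale_range must satisfy 0 < min <= max <= 1")
  abort_if(aspect_range[1] <= 0 || aspect_range[1] > aspect_range[2],
           "aspect_range must be a positive ordered range")
  if (length(crop_size) == 1L) crop_size <- c(crop_size, crop_size)
  h <- dim(img)[1]; w <- dim(img)[2]
  area <- h * w
  for (attempt in 1:10) {
    frac <- runif(1, scale_range[1], scale_range[2])
    ar <- exp(runif(1, log(aspect_range[1]), log(aspect_range[2])))
    cw <- as.integer(round(sqrt(area * frac * ar)))
    ch <- as.integer(round(sqrt(area * frac / ar)))
    if (cw >= 1 && ch >= 1 && cw <= w && ch <= h) {
      y0 <- sample.int(h - ch + 1L, 1) - 1L
      x0 <- sample.int(w - cw + 1L, 1) - 1L
      win <- img[y0 + seq_len(ch), x0 + seq_len(cw), , drop = FALSE]
      out <- resize_to(win, crop_size[1], crop_size[2])
      attr(out, "rr_draw") <- c(area_fraction = frac)
      return(out)
    }
  }
  s <- min(h, w)  # fallback: center crop of the shorter side
  y0 <- (h - s) %/% 2L; x0 <- (w - s) %/% 2L
  win <- img[y0 + seq_len(s), x0 + seq_len(s), , drop = FALSE]
  out <- resize_to(win, crop_size[1], crop_size[2])
  attr(out, "rr_draw") <- c(area_fraction = NA_real_)
  out
}
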