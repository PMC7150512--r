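# Field-of-view detection and the dermoscopy preprocessing chain.
#
# Uncropped dermoscopic images often show the illuminated circular field of
# view (FOV) surrounded by a large near-black border.  The chain below
# binarizes at a very low threshold, fits the ellipse with the same second
# central moments as the foreground, derives its axis-aligned bounding box,
# crops when a contrast heuristic says the border is genuinely dark, applies
# Shades-of-Gray color constancy, and resizes the longer side to a reference
# resolution.

#' Field-of-view pixel box
#'
#' Axis-aligned half-open pixel box `[x0, x1) x [y0, y1)`, 0-based,
#' x = column, y = row.
#'
#' @param x0,y0,x1,y1 integer pixel coordinates.
#' @return an object of class `fov_box`.
#' @export
fov_box <- function(x0, y0, x1, y1) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  abort_if(x0 >= x1 || y0 >= y1, "degenerate box: need x0 < x1 and y0 < y1")
  abort_if(x0 < 0 || y0 < 0, "box coordinates must be non-negative")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "fov_box")
}

#' @export
print.fov_box <- function(x, ...) {
  cat(sprintf("<fov_box [%d,%d) x [%d,%d)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

box_area <- function(b) (b$x1 - b$x0) * (b$y1 - b$y0)

#' Binarize an image for field-of-view detection
#'
#' Sets a pixel to 1 where its mean channel intensity exceeds a very low
#' threshold, so that the whole illuminated dermoscopy field of view becomes
#' foreground while the dark border stays background.
#'
#' @param img RGB array, grayscale matrix, or [image_record].
#' @param threshold intensity threshold on the \[0, 1\] scale; the default
#'   20/255 sits above sensor noise in the black border and below any skin
#'   tone.
#' @return integer matrix of 0/1, same spatial shape as the input.
#' @export
binarize_fov <- function(img, threshold = 20 / 255) {
  a <- as_image(img)
  check_image(a, allow_gray = TRUE)
  abort_if(threshold < 0 || threshold > 1, "threshold must be in [0, 1]")
  m <- channel_mean(a)
  mask <- matrix(0L, nrow(m), ncol(m))
  mask[m > threshold] <- 1L
  mask
}

#' Fit the equal-moments ellipse of a binary mask
#'
#' Computes the foreground center of mass and the ellipse having the same
#' second central moments as the foreground region.  Semi-axes follow the
#' standard equivalent-ellipse convention: semi-axis = 2 * sqrt(eigenvalue of
#' the second-central-moment matrix), so a filled disk of radius r yields
#' a = b = r and a full w x h rectangle yields w/sqrt(3), h/sqrt(3).
#'
#' @param mask 0/1 matrix from [binarize_fov()].
#' @return list with `cx`, `cy` (0-based pixel-center coordinates),
#'   `a` >= `b` (semi-axes, pixels) and `theta` (orientation of the major
#'   axis, radians in (-pi/2, pi/2]).
#' @export
fit_fov_ellipse <- function(mask) {
  abort_if(!is.matrix(mask), "mask must be a matrix")
  idx <- which(mask != 0, arr.ind = TRUE)
  abort_if(nrow(idx) == 0L, "no field of view found: mask has no foreground")
  y <- idx[, 1] - 1; x <- idx[, 2] - 1
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  M <- matrix(c(mu20, mu11, mu11, mu02), 2, 2)
  e <- eigen(M, symmetric = TRUE)
  abort_if(e$values[2] <= .Machine$double.eps,
           "degenerate mask: foreground has no two-dimensional spread")
  a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
  v <- e$vectors[, 1]
  theta <- atan2(v[2], v[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(cx = cx, cy = cy, a = a, b = b, theta = theta)
}

#' Bounding box of a (rotated) ellipse
#'
#' The tight axis-aligned box of an ellipse with semi-axes `a`, `b` rotated by
#' `theta` has half-extents `hx = sqrt(a^2 cos^2 t + b^2 sin^2 t)` and
#' `hy = sqrt(a^2 sin^2 t + b^2 cos^2 t)` around its centroid; the result is
#' clipped to the image bounds.
#'
#' @param e ellipse parameters from [fit_fov_ellipse()].
#' @param image_shape integer vector `c(height, width)`.
#' @return a [fov_box()].
#' @export
ellipse_to_bbox <- function(e, image_shape) {
  h <- image_shape[1]; w <- image_shape[2]
  ct <- cos(e$theta); st <- sin(e$theta)
  hx <- sqrt((e$a * ct)^2 + (e$b * st)^2)
  hy <- sqrt((e$a * st)^2 + (e$b * ct)^2)
  fov_box(max(0, floor(e$cx - hx)), max(0, floor(e$cy - hy)),
          min(w, ceiling(e$cx + hx)), min(h, ceiling(e$cy + hy)))
}

#' Crop-necessity heuristic parameters
#'
#' @param binarize_threshold FOV binarization threshold on \[0, 1\].
#' @param contrast_ratio how much brighter the inside of the candidate box
#'   must be than the outside for a crop to fire (dimensionless, >= 1).
#' @param min_outside_fraction minimum fraction of image area outside the box
#'   for a crop to be worthwhile.
#' @return parameter list of class `crop_params`.
#' @export
crop_params <- function(binarize_threshold = 20 / 255, contrast_ratio = 2,
                        min_outside_fraction = 0.05) {
  abort_if(binarize_threshold < 0 || binarize_threshold > 1,
           "binarize_threshold must be in [0, 1]")
  abort_if(contrast_ratio < 1, "contrast_ratio must be >= 1")
  abort_if(min_outside_fraction < 0 || min_outside_fraction > 1,
           "min_outside_fraction must be in [0, 1]")
  structure(list(binarize_threshold = binarize_threshold,
                 contrast_ratio = contrast_ratio,
                 min_outside_fraction = min_outside_fraction),
            class = "crop_params")
}

#' Decide whether cropping to a candidate box is warranted
#'
#' True iff the area outside the box is at least `min_outside_fraction` of
#' the image and the mean intensity inside the box is substantially brighter
#' than outside: `mean_inside >= contrast_ratio * (mean_outside + 1/255)`
#' (the small offset keeps the test meaningful when the border is pure
#' black).  A box covering the full image always returns `FALSE`.
#'
#' @param img RGB array or [image_record].
#' @param box candidate [fov_box()].
#' @param params a [crop_params()] list.
#' @return logical flag.
#' @export
needs_cropping <- function(img, box, params = crop_params()) {
  a <- as_image(img)
  check_image(a)
  h <- dim(a)[1]; w <- dim(a)[2]
  abort_if(box$x1 > w || box$y1 > h, "box exceeds image bounds")
  total <- h * w
  outside_n <- total - box_area(box)
  if (outside_n / total < params$min_outside_fraction) return(FALSE)
  m <- channel_mean(a)
  inside <- m[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1]
  mean_inside <- mean(inside)
  mean_outside <- (sum(m) - sum(inside)) / outside_n
  mean_inside >= params$contrast_ratio * (mean_outside + 1 / 255)
}

#' Automatically crop away a dark border around the field of view
#'
#' Composition of [binarize_fov()], [fit_fov_ellipse()], [ellipse_to_bbox()]
#' and [needs_cropping()]: the image is cropped to the detected box only when
#' the heuristic fires; otherwise it is returned unchanged.  An all-dark image
#' (no foreground after binarization) is returned unchanged with a warning.
#'
#' @param img RGB array or [image_record].
#' @param params a [crop_params()] list.
#' @return list with `image` (same kind as input), `box` (the [fov_box()]
#'   used, or `NULL` when detection failed) and `cropped` (logical).
#' @export
auto_crop <- function(img, params = crop_params()) {
  a <- as_image(img)
  check_image(a)
  mask <- binarize_fov(a, params$binarize_threshold)
  e <- tryCatch(fit_fov_ellipse(mask), error = function(err) {
    warning(conditionMessage(err), call. = FALSE)
    NULL
  })
  if (is.null(e)) return(list(image = img, box = NULL, cropped = FALSE))
  box <- ellipse_to_bbox(e, dim(a))
  if (!needs_cropping(a, box, params))
    return(list(image = img, box = box, cropped = FALSE))
  out <- crop_to_box(a, box)
  list(image = with_image(img, out, cropped = TRUE), box = box, cropped = TRUE)
}

#' Shades-of-Gray color constancy
#'
#' Estimates the illuminant per channel as the Minkowski p-norm mean
#' `e_c = (mean(I_c^p))^(1/p)` (p = 6 by default) and rescales each channel by
#' `g / e_c`, where the gain `g` is the arithmetic mean of the three channel
#' illuminants so overall brightness is preserved.  Output is clipped to
#' \[0, 1\].  A channel that is identically zero is left unchanged with a
#' warning (its illuminant is undefined).
#'
#' @param img RGB array or [image_record].
#' @param p Minkowski norm order (> 0; default 6).
#' @return object of the same kind as `img`.
#' @export
shades_of_gray <- function(img, p = 6) {
  a <- as_image(img)
  check_image(a)
  abort_if(p <= 0, "p must be positive")
  e <- vapply(1:3, function(c) mean(a[, , c]^p)^(1 / p), numeric(1))
  if (any(e == 0)) {
    warning("channel with zero illuminant left unchanged", call. = FALSE)
  }
  g <- mean(e[e > 0])
  if (!is.finite(g)) return(img)   # fully black image
  out <- a
  for (c in 1:3) if (e[c] > 0) out[, , c] <- a[, , c] * (g / e[c])
  with_image(img, clip01(out))
}

#' Full dermoscopy preprocessing chain
#'
#' Applies, in order: automatic FOV cropping ([auto_crop()]), Shades-of-Gray
#' color constancy ([shades_of_gray()]), and aspect-preserving resize of the
#' longer side ([resize_longer_side()]).  When given an [image_record()] the
#' `cropped` and `preprocessed` provenance flags are updated.
#'
#' @param img RGB array or [image_record].
#' @param params a [crop_params()] list.
#' @param sog_p Minkowski norm order for color constancy.
#' @param target longer-side resize target in pixels.
#' @return list with `image`, `box`, `cropped` as in [auto_crop()].
#' @export
preprocess <- function(img, params = crop_params(), sog_p = 6, target = 600L) {
  cr <- auto_crop(img, params)
  out <- shades_of_gray(cr$image, p = sog_p)
  out <- resize_longer_side(out, target = target)
  out <- with_image(out, as_image(out), preprocessed = TRUE)
  list(image = out, box = cr$box, cropped = cr$cropped)
}
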