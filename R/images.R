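#' @importFrom stats rnorm runif rexp setNames sd
#' @importFrom utils read.csv write.csv
#' @importFrom grDevices hsv col2rgb
NULL

# Image convention used throughout the package:
#   numeric array dim = c(height, width, 3), intensities in [0, 1],
#   x = column index, y = row index, both 0-based in all public APIs,
#   boxes half-open [x0, x1) x [y0, y1).

abort_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Validate an RGB image array
#'
#' Checks that `img` follows the package image convention: a numeric array of
#' dimension `height x width x 3` (or `height x width` for grayscale masks)
#' with finite values.
#'
#' @param img object to check.
#' @param allow_gray accept a 2-d grayscale array.
#' @return `img`, invisibly.
#' @export
check_image <- function(img, allow_gray = FALSE) {
  abort_if(!is.numeric(img), "image must be a numeric array")
  d <- dim(img)
  ok <- (length(d) == 3L && d[3] == 3L) || (allow_gray && length(d) == 2L)
  abort_if(!ok, "image must be an h x w x 3 array (or h x w if grayscale allowed)")
  abort_if(any(d[1:2] < 1L), "empty image")
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Per-pixel mean channel intensity
#'
#' @param img RGB image array, or a grayscale matrix (returned unchanged).
#' @return matrix `height x width` of channel means.
#' @export
channel_mean <- function(img) {
  check_image(img, allow_gray = TRUE)
  if (length(dim(img)) == 2L) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

#' Construct an image record
#'
#' An image record bundles pixel data with its identifiers and provenance
#' flags, mirroring one row of an ISIC-style dataset.
#'
#' @param image RGB array per the package convention.
#' @param image_id character id.
#' @param lesion_id character lesion id (several images may share one).
#' @param label integer class index in 0..8 or `NA`.
#' @param cropped,preprocessed provenance flags.
#' @return an object of class `image_record`.
#' @export
image_record <- function(image, image_id, lesion_id = image_id, label = NA_integer_,
                         cropped = FALSE, preprocessed = FALSE) {
  check_image(image)
  structure(
    list(image = image, image_id = as.character(image_id),
         lesion_id = as.character(lesion_id), label = label,
         cropped = isTRUE(cropped), preprocessed = isTRUE(preprocessed)),
    class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<image_record %s  %dx%d  lesion=%s  label=%s  cropped=%s preprocessed=%s>\n",
              x$image_id, d[2], d[1], x$lesion_id,
              ifelse(is.na(x$label), "NA", x$label), x$cropped, x$preprocessed))
  invisible(x)
}

as_image <- function(x) {
  if (inherits(x, "image_record")) x$image else x
}

with_image <- function(rec, img, ...) {
  if (!inherits(rec, "image_record")) return(img)
  rec$image <- img
  extra <- list(...)
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  rec
}

# Conversions to/from EBImage (dim = width x height x channel)
to_eb <- function(img) {
  if (length(dim(img)) == 2L)
    EBImage::Image(t(img))
  else
    EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
}

from_eb <- function(eb) {
  a <- EBImage::imageData(eb)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
}

#' Read / write PNG images
#'
#' Thin wrappers around the `png` package adapting to the package's
#' `height x width x 3` array convention.
#'
#' @param path file path.
#' @param img RGB array.
#' @return `read_image_png` returns an RGB array; `write_image_png` returns
#'   `path` invisibly.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]
  a
}

#' @rdname read_image_png
#' @export
write_image_png <- function(img, path) {
  check_image(img)
  png::writePNG(clip01(img), path)
  invisible(path)
}

#' Resize an image so its longer side equals a target
#'
#' Downscales with bilinear interpolation (antialiased) so that the longer
#' side equals `target` pixels, preserving the aspect ratio to within one
#' pixel of rounding.  Images whose longer side is already at or below the
#' target are returned unchanged: only larger images are shrunk, smaller ones
#' are never upscaled.
#'
#' @param img RGB array or [image_record].
#' @param target target length in pixels of the longer side (default 600,
#'   the HAM10000 reference resolution).
#' @return object of the same kind as `img`.
#' @export
resize_longer_side <- function(img, target = 600L) {
  a <- as_image(img)
  check_image(a)
  h <- dim(a)[1]; w <- dim(a)[2]
  longer <- max(h, w)
  if (longer <= target) return(img)
  s <- target / longer
  nh <- if (h >= w) target else max(1L, as.integer(round(h * s)))
  nw <- if (w > h)  target else max(1L, as.integer(round(w * s)))
  out <- from_eb(EBImage::resize(to_eb(a), w = nw, h = nh, antialias = TRUE))
  out <- clip01(out)
  with_image(img, out)
}

#' Resize an image to exact dimensions
#'
#' @param img RGB array.
#' @param h,w output dimensions in pixels.
#' @return resized RGB array.
#' @export
resize_to <- function(img, h, w) {
  check_image(img)
  if (dim(img)[1] == h && dim(img)[2] == w) return(img)
  clip01(from_eb(EBImage::resize(to_eb(img), w = w, h = h, antialias = TRUE)))
}

#' Crop an image to a half-open pixel box
#'
#' @param img RGB array.
#' @param box a [fov_box()].
#' @return cropped RGB array.
#' @export
crop_to_box <- function(img, box) {
  check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  abort_if(box$x0 < 0 || box$y0 < 0 || box$x1 > w || box$y1 > h,
           "box exceeds image bounds")
  img[(box$y0 + 1L):box$y1, (box$x0 + 1L):box$x1, , drop = FALSE]
}

# Pad an image with zeros (black) to at least (h, w), content centered.
pad_to <- function(img, h, w) {
  d <- dim(img)
  if (d[1] >= h && d[2] >= w) return(img)
  nh <- max(d[1], h); nw <- max(d[2], w)
  out <- array(0, c(nh, nw, d[3]))
  y0 <- (nh - d[1]) %/% 2L; x0 <- (nw - d[2]) %/% 2L
  out[y0 + seq_len(d[1]), x0 + seq_len(d[2]), ] <- img
  out
}

# Apply a 3x3 affine matrix (output coords = T %*% input coords, homogeneous,
# x = column, y = row, origin at the first pixel) via EBImage, output same size.
affine_warp <- function(img, Tm) {
  m <- t(Tm[1:2, ])               # EBImage wants row-vector forward mapping
  eb <- EBImage::affine(to_eb(img), m, filter = "bilinear",
                        output.dim = c(dim(img)[2], dim(img)[1]),
                        antialias = FALSE)
  clip01(from_eb(eb))
}

# Compose center-based rotation / scale / shear into a 3x3 forward matrix.
make_affine <- function(w, h, angle_deg = 0, scale = 1, shear_deg = 0) {
  th <- angle_deg * pi / 180
  sh <- tan(shear_deg * pi / 180)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  S <- diag(c(scale, scale, 1))
  H <- matrix(c(1, 0, 0, sh, 1, 0, 0, 0, 1), 3, 3)
  cx <- w / 2; cy <- h / 2
  Tc  <- matrix(c(1, 0, 0, 0, 1, 0, cx, cy, 1), 3, 3)
  Tmc <- matrix(c(1, 0, 0, 0, 1, 0, -cx, -cy, 1), 3, 3)
  Tc %*% (S %*% R %*% H) %*% Tmc
}
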