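# Stochastic augmentation: identity at zero magnitudes, reproducibility,
# CutOut geometry, crop-offset uniformity, and random-resize-crop ranges.

identity_params <- function() {
  augment_params(brightness_range = c(0, 0), contrast_range = c(1, 1),
                 rotation_range = c(0, 0), scale_range = c(1, 1),
                 shear_range = c(0, 0), hflip_prob = 0, vflip_prob = 0,
                 cutout_holes = 0L)
}

test_that("zero-magnitude augmentation is the identity and seeds reproduce", {
  img <- gradient_image(24, 30)
  out <- random_augment(img, identity_params())
  attr(out, "augment_draw") <- NULL
  expect_equal(out, img, tolerance = 1e-12)

  set.seed(99); a <- random_augment(img, augment_params())
  set.seed(99); b <- random_augment(img, augment_params())
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), dim(img))
})

test_that("sampled rotation angles are uniform over the configured range", {
  img <- gradient_image(16, 16)
  p <- augment_params(cutout_holes = 0L)
  set.seed(7)
  angles <- replicate(1000, attr(random_augment(img, p), "augment_draw")$angle)
  # mean of U(-180, 180) is 0; 99% CI half-width = 2.58 * 180/sqrt(3)/sqrt(1000)
  expect_lt(abs(mean(angles)), 2.58 * 180 / sqrt(3) / sqrt(1000))
  expect_true(all(angles >= -180 & angles <= 180))
})

test_that("cutout zeroes exactly the clipped square", {
  img <- array(1, c(64, 64, 3))
  # interior hole: exactly 16 x 16 pixels zeroed in every channel
  set.seed(10)
  repeat {
    out <- cutout(img, 1L, 16L)
    zeroed <- sum(out[, , 1] == 0)
    if (zeroed == 256) break   # found an interior draw
  }
  expect_equal(sum(out == 0), 256 * 3)

  # a hole centered at the corner pixel keeps only its visible 8 x 8 quadrant
  set.seed(42)
  found_corner <- FALSE
  for (i in 1:20000) {
    o <- cutout(img, 1L, 16L)
    dark_rows <- which(apply(o[, , 1], 1, min) == 0)
    dark_cols <- which(apply(o[, , 1], 2, min) == 0)
    if (identical(dark_rows, 1:8) && identical(dark_cols, 1:8)) {
      expect_equal(sum(o[, , 1] == 0), 64)  # 8 x 8 after border clipping
      found_corner <- TRUE
      break
    }
  }
  expect_true(found_corner)

  expect_identical(cutout(img, 0L, 16L), img)
  expect_error(cutout(array(1, c(8, 8, 3)), 1L, 16L), "exceed")
})

test_that("same-size crops are contiguous windows with uniform offsets", {
  img <- gradient_image(20, 26)
  same <- same_size_crop(img, c(20, 26))
  attr(same, "crop_offset") <- NULL
  expect_identical(same, img)

  set.seed(8)
  crop <- same_size_crop(img, c(8, 8))
  off <- attr(crop, "crop_offset")
  expect_equal(dim(crop), c(8, 8, 3))
  expect_equal(crop[, , 1], img[off["y"] + 1:8, off["x"] + 1:8, 1],
               ignore_attr = TRUE)

  # offsets uniform over the 13 valid x positions (chi-square, p > 0.01)
  set.seed(12)
  xs <- replicate(10000, attr(same_size_crop(img, c(20, 14)), "crop_offset")["x"])
  tab <- table(factor(xs, levels = 0:12))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)

  # smaller image: padded then cropped to exact size
  tiny <- gradient_image(5, 5)
  padded <- same_size_crop(tiny, c(9, 9))
  expect_equal(dim(padded), c(9, 9, 3))
})

test_that("random-resize crop respects area range and output size", {
  img <- gradient_image(40, 40)
  set.seed(4)
  fracs <- replicate(500, {
    out <- random_resize_crop(img, 16, scale_range = c(0.3, 0.9))
    expect_equal(dim(out), c(16, 16, 3))
    attr(out, "rr_draw")[["area_fraction"]]
  })
  drawn <- fracs[!is.na(fracs)]
  expect_gt(length(drawn), 400)
  expect_true(all(drawn >= 0.3 & drawn <= 0.9))

  # full-area square sample is the resized full image
  set.seed(5)
  out <- random_resize_crop(img, 20, scale_range = c(1, 1), aspect_range = c(1, 1))
  expect_equal(out, resize_to(img, 20, 20), ignore_attr = TRUE)
})
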