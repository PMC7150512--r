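# FOV binarization, moment-ellipse fitting, bounding boxes, crop heuristic,
# Shades-of-Gray color constancy, and the resize step.

test_that("binarization separates FOV from dark border", {
  bright <- array(0.5, c(10, 12, 3))
  expect_true(all(binarize_fov(bright, 20 / 255) == 1))
  dark <- array(0, c(10, 12, 3))
  expect_true(all(binarize_fov(dark) == 0))

  g <- gen_dermoscopy_image(synthetic_image_spec(200, 160, c(100, 80), 70, seed = 4))
  mask <- binarize_fov(g$record$image)
  xg <- matrix(rep(0:199, each = 160), 160, 200)
  yg <- matrix(rep(0:159, times = 200), 160, 200)
  disk <- ((xg - 100)^2 + (yg - 80)^2 <= 70^2) * 1L
  jaccard <- sum(mask & disk) / sum(mask | disk)
  expect_gte(jaccard, 0.99)
})

test_that("equal-moments ellipse recovers analytic shapes", {
  # centered disk: a = b = radius within 1.5% discretization error
  m <- matrix(0L, 220, 220)
  xg <- col(m) - 1; yg <- row(m) - 1
  m[(xg - 110)^2 + (yg - 110)^2 <= 90^2] <- 1L
  e <- fit_fov_ellipse(m)
  expect_lt(abs(e$a - 90) / 90, 0.015)
  expect_lt(abs(e$b - 90) / 90, 0.015)
  expect_equal(e$cx, 110, tolerance = 1e-6)
  expect_equal(e$cy, 110, tolerance = 1e-6)

  # full rectangle: semi-axes L / sqrt(3) (uniform second moment L^2 / 12)
  r <- matrix(1L, 60, 100)
  er <- fit_fov_ellipse(r)
  expect_equal(er$a, 100 / sqrt(3), tolerance = 0.02)
  expect_equal(er$b, 60 / sqrt(3), tolerance = 0.02)

  # translation equivariance
  base <- matrix(0L, 120, 120)
  base[31:60, 21:70] <- 1L
  shifted <- matrix(0L, 120, 120)
  shifted[41:70, 46:95] <- 1L  # dy = 10, dx = 25
  e0 <- fit_fov_ellipse(base); e1 <- fit_fov_ellipse(shifted)
  expect_equal(e1$cx - e0$cx, 25)
  expect_equal(e1$cy - e0$cy, 10)
  expect_equal(e1$a, e0$a)
  expect_equal(e1$b, e0$b)

  expect_error(fit_fov_ellipse(matrix(0L, 5, 5)), "no field of view")
  line <- matrix(0L, 10, 10); line[4, ] <- 1L
  expect_error(fit_fov_ellipse(line), "degenerate")
})

test_that("ellipse bounding boxes are tight and contain the region", {
  b <- ellipse_to_bbox(list(cx = 300, cy = 225, a = 200, b = 200, theta = 0),
                       c(450, 600))
  expect_equal(unclass(b)[c("x0", "y0", "x1", "y1")],
               list(x0 = 100L, y0 = 25L, x1 = 500L, y1 = 425L))
  b2 <- ellipse_to_bbox(list(cx = 200, cy = 200, a = 100, b = 50, theta = 0),
                        c(400, 400))
  expect_equal(unclass(b2)[c("x0", "y0", "x1", "y1")],
               list(x0 = 100L, y0 = 150L, x1 = 300L, y1 = 250L))
  # random orientations: box contains every pixel of the exact ellipse mask
  set.seed(11)
  for (i in 1:25) {
    a <- runif(1, 20, 60); bb <- runif(1, 10, a); th <- runif(1, -pi / 2, pi / 2)
    cx <- runif(1, 70, 130); cy <- runif(1, 70, 130)
    mask <- rasterize_ellipse(200, 200, cx, cy, a, bb, th)
    box <- ellipse_to_bbox(list(cx = cx, cy = cy, a = a, b = bb, theta = th),
                           c(200, 200))
    fg <- which(mask == 1, arr.ind = TRUE)
    x <- fg[, 2] - 1; y <- fg[, 1] - 1
    expect_true(all(x >= box$x0 & x < box$x1 & y >= box$y0 & y < box$y1))
  }
})

test_that("crop heuristic fires on dark borders and never on uniform images", {
  uni <- array(0.4, c(100, 100, 3))
  expect_false(needs_cropping(uni, fov_box(10, 10, 90, 90)))
  expect_false(needs_cropping(uni, fov_box(0, 0, 100, 100)))
  g <- gen_dermoscopy_image(synthetic_image_spec(240, 200, c(120, 100), 80, seed = 2))
  expect_true(needs_cropping(g$record$image, g$gt_box))
})

test_that("auto_crop recovers synthetic FOV boxes and leaves the rest alone", {
  set.seed(21)
  n <- 60; hits <- 0
  for (i in 1:n) {
    w <- sample(180:300, 1); h <- sample(150:260, 1)
    r <- runif(1, 0.28, 0.45) * min(w, h)
    cx <- runif(1, r + 2, w - r - 2); cy <- runif(1, r + 2, h - r - 2)
    g <- gen_dermoscopy_image(synthetic_image_spec(w, h, c(cx, cy), r,
                                                   lesion_class = sample(0:8, 1),
                                                   seed = 5000 + i))
    ac <- auto_crop(g$record)
    expect_true(ac$cropped)
    err <- max(abs(ac$box$x0 - g$gt_box$x0), abs(ac$box$x1 - g$gt_box$x1),
               abs(ac$box$y0 - g$gt_box$y0), abs(ac$box$y1 - g$gt_box$y1))
    if (err <= 3) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)

  full <- gen_dermoscopy_image(synthetic_image_spec(140, 120, fov_radius = 0, seed = 8))
  acf <- auto_crop(full$record)
  expect_false(acf$cropped)
  expect_identical(acf$image$image, full$record$image)

  black <- array(0, c(50, 60, 3))
  expect_warning(acb <- auto_crop(black), "no field of view")
  expect_false(acb$cropped)
  expect_identical(acb$image, black)
})

test_that("auto_crop is stable under repetition", {
  for (i in 1:5) {
    g <- gen_dermoscopy_image(synthetic_image_spec(220, 200, c(110, 100),
                                                   70 + 4 * i, seed = 300 + i))
    first <- auto_crop(g$record$image)
    second <- auto_crop(first$image)
    a1 <- prod(dim(first$image)[1:2])
    kept <- if (second$cropped) with(second$box, (x1 - x0) * (y1 - y0)) else a1
    expect_gte(kept / a1, 0.99)
  }
})

test_that("shades of gray equalizes channel illuminants", {
  # achromatic fixed point
  gray <- array(rep(matrix(0.3, 20, 20), 3), c(20, 20, 3))
  expect_equal(shades_of_gray(gray), gray, tolerance = 1e-12)
  # uniform color becomes achromatic (channels equal) before clipping
  uc <- array(rep(c(120, 60, 180) / 255, each = 400), c(20, 20, 3))
  out <- shades_of_gray(uc)
  expect_lt(max(abs(out[, , 1] - out[, , 2])), 1e-12)
  expect_lt(max(abs(out[, , 2] - out[, , 3])), 1e-12)
  # property: post-correction Minkowski-6 means equal (no clipping at <= 0.5)
  set.seed(31)
  for (i in 1:10) {
    img <- array(runif(30 * 40 * 3, 0, 0.5) * rep(runif(3, 0.3, 1), each = 1200),
                 c(30, 40, 3))
    o <- shades_of_gray(img)
    e <- vapply(1:3, function(c) mean(o[, , c]^6)^(1 / 6), numeric(1))
    expect_lt(diff(range(e)) / mean(e), 1e-4)
  }
  # zero channel guard
  z <- array(0.4, c(10, 10, 3)); z[, , 2] <- 0
  expect_warning(oz <- shades_of_gray(z), "zero illuminant")
  expect_equal(oz[, , 2], z[, , 2])
})

test_that("resize_longer_side hits the target, preserves aspect, is idempotent", {
  big <- array(0.5, c(1024, 1024, 3))
  expect_equal(dim(resize_longer_side(big))[1:2], c(600, 600))
  wide <- array(0.5, c(900, 1200, 3))
  expect_equal(dim(resize_longer_side(wide))[1:2], c(450, 600))
  small <- array(0.5, c(300, 400, 3))
  expect_identical(resize_longer_side(small), small)
  once <- resize_longer_side(wide)
  expect_identical(resize_longer_side(once), once)
})

test_that("full preprocessing chain crops, normalizes and resizes", {
  g <- gen_dermoscopy_image(synthetic_image_spec(1024, 1024, c(512, 512), 460,
                                                 lesion_class = 1, seed = 13))
  pp <- preprocess(g$record)
  expect_true(pp$cropped)
  expect_true(pp$image$preprocessed)
  expect_equal(max(dim(pp$image$image)[1:2]), 600)
  flat <- array(0.45, c(450, 600, 3))
  ppf <- preprocess(flat)
  expect_false(ppf$cropped)
  expect_equal(dim(ppf$image), dim(flat))
})
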