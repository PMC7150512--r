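# Synthetic fixture generator: geometry of ground-truth boxes, determinism,
# lesion grouping, metadata missingness, and prediction-tensor calibration.

test_that("disk ground-truth box circumscribes the FOV and full-frame is identity", {
  g <- gen_dermoscopy_image(synthetic_image_spec(600, 450, c(300, 225), 200,
                                                 lesion_class = 2, seed = 7))
  expect_equal(unclass(g$gt_box)[c("x0", "y0", "x1", "y1")],
               list(x0 = 100L, y0 = 25L, x1 = 500L, y1 = 425L))
  expect_equal(dim(g$record$image), c(450, 600, 3))

  full <- gen_dermoscopy_image(synthetic_image_spec(120, 90, fov_radius = 0, seed = 3))
  expect_equal(unclass(full$gt_box)[c("x0", "y0", "x1", "y1")],
               list(x0 = 0L, y0 = 0L, x1 = 120L, y1 = 90L))
})

test_that("identical spec and seed reproduce identical pixels; seeds differ", {
  for (i in 1:20) {
    spec <- synthetic_image_spec(60 + i, 50 + i, fov_radius = 20,
                                 lesion_class = i %% 9, seed = 1000 + i)
    a <- gen_dermoscopy_image(spec)$record$image
    b <- gen_dermoscopy_image(spec)$record$image
    expect_identical(a, b)
  }
  s1 <- synthetic_image_spec(64, 64, fov_radius = 25, seed = 1)
  s2 <- synthetic_image_spec(64, 64, fov_radius = 25, seed = 2)
  expect_false(identical(gen_dermoscopy_image(s1)$record$image,
                         gen_dermoscopy_image(s2)$record$image))
})

test_that("invalid image specs are rejected", {
  expect_error(synthetic_image_spec(4, 4), "at least 8")
  expect_error(synthetic_image_spec(100, 100, fov_radius = 60), "at most")
  expect_error(synthetic_image_spec(100, 100, lesion_class = 9), "0..8")
})

test_that("lesion datasets group images by lesion with shared labels", {
  spec <- synthetic_dataset_spec(n_lesions = 10, images_per_lesion = 3,
                                 image_size = c(32, 32), seed = 5)
  ds <- gen_lesion_dataset(spec)
  expect_length(ds$records, 30)
  expect_length(unique(ds$lesion_ids), 10)
  for (lid in unique(ds$lesion_ids))
    expect_length(unique(ds$labels[ds$lesion_ids == lid]), 1)
  # no missing metadata at rate zero
  expect_false(anyNA(ds$meta))
  # ages are multiples of five
  expect_true(all(ds$meta$age_approx %% 5 == 0))
})

test_that("metadata fields go missing at the configured rate", {
  spec <- synthetic_dataset_spec(n_lesions = 5000, images_per_lesion = 1,
                                 image_size = c(16, 16), fov_radius_range = c(0, 0),
                                 metadata_missing_rates = c(age = .1, site = .1, sex = .1),
                                 seed = 77)
  ds <- gen_lesion_dataset(spec)
  fracs <- c(mean(is.na(ds$meta$age_approx)),
             mean(is.na(ds$meta$anatom_site_general)),
             mean(is.na(ds$meta$sex)))
  # binomial 99% interval around 0.1 at n = 5000 is well inside [0.08, 0.12]
  expect_true(all(fracs > 0.08 & fracs < 0.12))
})

test_that("dataset validation rejects degenerate specs", {
  expect_error(synthetic_dataset_spec(0), "positive")
  expect_error(synthetic_dataset_spec(5, class_probabilities = rep(0.2, 9)),
               "sum to 1")
})

test_that("prediction tensors are row-stochastic and calibrated to skill", {
  # skill 1: every configuration classifies perfectly
  pt1 <- gen_prediction_tensor(synthetic_prediction_spec(3, 2, 50, 9, skill = 1, seed = 1))
  for (i in 1:3) {
    S <- mean_sensitivity(unlist(pt1$labels),
                          do.call(rbind, pt1$preds[[i]]), C_cls = 9)
    expect_equal(S, 1)
  }
  # skill 0: chance level, about 1/9 (99% binomial bound at n = 2000)
  pt0 <- gen_prediction_tensor(synthetic_prediction_spec(1, 4, 500, 9, skill = 0, seed = 2))
  S0 <- mean_sensitivity(unlist(pt0$labels), do.call(rbind, pt0$preds[[1]]), C_cls = 9)
  expect_lt(abs(S0 - 1 / 9), 0.03)
  # shape and simplex invariants
  expect_equal(pt0$n_folds, 4)
  for (j in 1:4) {
    p <- pt0$preds[[1]][[j]]
    expect_equal(dim(p), c(500, 9))
    expect_true(all(p >= 0))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  }
  expect_error(synthetic_prediction_spec(2, n_classes = 1), "at least 2")
})

test_that("datasets round-trip through the ISIC directory layout", {
  dir <- withr::local_tempdir()
  ds <- gen_lesion_dataset(synthetic_dataset_spec(4, 2, image_size = c(24, 24),
                                                  seed = 9))
  write_lesion_dataset(ds, dir)
  expect_length(list.files(file.path(dir, "images"), pattern = "\\.png$"), 8)
  gt <- read.csv(file.path(dir, "groundtruth.csv"))
  expect_identical(names(gt), c("image", isic_classes()))
  expect_true(all(rowSums(gt[, -1]) == 1))
  expect_equal(max.col(gt[, -1]) - 1L, ds$labels)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_identical(names(meta), c("image", "age_approx", "anatom_site_general", "sex"))
  img <- read_image_png(file.path(dir, "images", paste0(ds$records[[1]]$image_id, ".png")))
  expect_equal(dim(img), c(24, 24, 3))
  expect_lt(max(abs(img - ds$records[[1]]$image)), 1 / 255)
})
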