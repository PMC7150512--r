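# Class weighting, weighted cross-entropy, the LR schedule, lesion-grouped
# CV splitting, and two-branch architecture arithmetic.

test_that("class weights follow (N/N_i)^k with its algebraic identity", {
  cw <- class_weights(c(90, 10), k = 1)
  expect_equal(cw$weights, c(100 / 90, 10))
  expect_equal(class_weights(c(7, 13, 5), k = 0)$weights, c(1, 1, 1))
  set.seed(2)
  for (i in 1:20) {
    counts <- sample(1:500, sample(2:9, 1), replace = TRUE)
    cw <- class_weights(counts, k = 1)
    # sum N_i * (N/N_i) = C * N
    expect_equal(sum(counts * cw$weights), length(counts) * sum(counts))
    # monotone: rarer class, larger weight (k > 0)
    expect_true(all(diff(cw$weights[order(counts)]) <= 1e-9))
  }
  expect_error(class_weights(c(5, 0, 3)), "zero")
})

test_that("weighted cross-entropy matches closed forms and a per-sample oracle", {
  # perfect predictions: loss ~ 0
  logits <- matrix(-1000, 4, 9)
  logits[cbind(1:4, c(1, 3, 5, 9))] <- 1000
  ce <- weighted_cross_entropy(logits, c(0, 2, 4, 8), rep(1, 9))
  expect_lt(ce$loss, 1e-6)
  # uniform predictions, unit weights: loss = ln 9
  ceu <- weighted_cross_entropy(matrix(0, 5, 9), c(0, 1, 2, 3, 4), rep(1, 9))
  expect_equal(ceu$loss, log(9), tolerance = 1e-12)
  # random batches vs brute-force per-sample oracle
  set.seed(3)
  for (i in 1:25) {
    n <- sample(2:20, 1); K <- sample(2:9, 1)
    logits <- matrix(rnorm(n * K, sd = 3), n, K)
    labels <- sample(0:(K - 1), n, replace = TRUE)
    w <- runif(K, 0.5, 10)
    ce <- weighted_cross_entropy(logits, labels, w)
    expect_equal(ce$loss, oracle_weighted_ce(logits, labels, w),
                 tolerance = 1e-9)
    # gradient sums to zero across classes for each sample only when
    # weighted; check the analytic colSum identity instead: rows sum to 0
    expect_lt(max(abs(rowSums(ce$dlogits))), 1e-12)
  }
  expect_error(weighted_cross_entropy(matrix(0, 2, 3), c(0, 5), rep(1, 3)),
               "out of range")
})

test_that("loss gradient agrees with numerical differentiation", {
  set.seed(4)
  logits <- matrix(rnorm(3 * 4), 3, 4)
  labels <- c(0, 2, 3)
  w <- c(1, 2, 0.5, 4)
  ce <- weighted_cross_entropy(logits, labels, w)
  eps <- 1e-6
  for (i in 1:3) for (j in 1:4) {
    lp <- logits; lp[i, j] <- lp[i, j] + eps
    lm <- logits; lm[i, j] <- lm[i, j] - eps
    num <- (weighted_cross_entropy(lp, labels, w)$loss -
              weighted_cross_entropy(lm, labels, w)$loss) / (2 * eps)
    expect_equal(ce$dlogits[i, j], num, tolerance = 1e-5)
  }
})

test_that("learning rate halves every 25 epochs", {
  expect_equal(lr_schedule(0, 0.01), 0.01)
  expect_equal(lr_schedule(24, 0.01), 0.01)
  expect_equal(lr_schedule(25, 0.01), 0.005)
  expect_equal(lr_schedule(99, 0.01), 0.01 / 8)
  expect_equal(lr_schedule(10, 0.02, period = 5), 0.02 / 4)
})

test_that("grouped k-fold keeps all images of a lesion in one fold", {
  ids <- rep(sprintf("L%02d", 1:10), each = 3)
  split <- grouped_kfold(ids, n_folds = 5, seed = 1)
  expect_equal(split$n_folds, 5)
  folds_per_lesion <- tapply(split$fold, ids, function(f) length(unique(f)))
  expect_true(all(folds_per_lesion == 1))
  expect_equal(unname(table(split$fold)), rep(6L, 5), ignore_attr = TRUE)

  # property: zero leakage for arbitrary structures
  set.seed(6)
  for (i in 1:50) {
    nl <- sample(5:40, 1)
    ids <- sample(rep(sprintf("L%03d", 1:nl), sample(1:4, nl, replace = TRUE)))
    sp <- grouped_kfold(ids, n_folds = sample(2:5, 1), seed = i)
    expect_true(all(tapply(sp$fold, ids, function(f) length(unique(f))) == 1))
  }
  expect_error(grouped_kfold(c("a", "b"), n_folds = 5), "at least 5")
})

test_that("train-only records join every training set and no validation set", {
  ids <- c(rep(sprintf("L%02d", 1:10), each = 2), "EXT1", "EXT1", "EXT2")
  train_only <- c(rep(FALSE, 20), TRUE, TRUE, TRUE)
  split <- grouped_kfold(ids, n_folds = 5, seed = 3, train_only = train_only)
  expect_true(all(is.na(split$fold[21:23])))
  for (j in 1:5) {
    fi <- cv_fold_indices(split, j)
    expect_true(all(21:23 %in% fi$train))
    expect_false(any(21:23 %in% fi$val))
    expect_length(intersect(fi$train, fi$val), 0)
  }
})

test_that("two-branch architecture has the declared widths and modes", {
  bb <- tiny_backbone(c(32, 32), channels = c(8, 16, 64))
  expect_equal(bb$feature_width, 64)
  m <- build_two_branch_model(bb, meta_branch_spec(fusion_units = 128),
                              mode = "meta", seed = 1)
  # fusion layer consumes backbone features (64) + meta branch output (256)
  expect_equal(dim(m$params$head$fusion$W), c(64 + 256, 128))
  expect_equal(dim(m$params$head$meta1$W), c(11, 256))
  expect_equal(dim(m$params$head$classifier$W), c(128, 9))

  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  meta <- matrix(runif(4 * 11), 4, 11)
  fw <- dermpipe:::model_forward(m, x, meta, train = FALSE)
  expect_equal(dim(fw$logits), c(4, 9))

  mi <- build_two_branch_model(bb, mode = "image_only", seed = 2)
  fwi <- dermpipe:::model_forward(mi, x, NULL, train = FALSE)
  expect_equal(dim(fwi$logits), c(4, 9))
  expect_error(dermpipe:::model_forward(mi, x, meta), "image-only")
  expect_error(dermpipe:::model_forward(m, x, NULL), "requires")
})
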