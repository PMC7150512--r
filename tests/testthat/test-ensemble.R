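# Prediction tensors, subset averaging, the exhaustive search, and
# best/last pooling.

make_tensor <- function(skill, n_configs = length(skill), seed = 1,
                        n_folds = 3, n_img = 40) {
  gen_prediction_tensor(synthetic_prediction_spec(
    n_configs, n_folds, n_img, 9, skill = skill, seed = seed))
}

test_that("tensor validation catches misshapen or non-stochastic inputs", {
  pt <- make_tensor(c(0.5, 0.5))
  expect_equal(pt$n_configs, 2)
  bad <- pt$preds
  bad[[1]][[1]][1, ] <- bad[[1]][[1]][1, ] * 2
  expect_error(prediction_tensor(bad, pt$labels), "probability")
  short <- pt$labels; short[[1]] <- short[[1]][-1]
  expect_error(prediction_tensor(pt$preds, short), "labels")
})

test_that("ensemble averaging matches the nested-mean oracle and idempotence", {
  pt <- make_tensor(c(0.2, 0.6, 0.9), seed = 4)
  # singleton subset: unchanged predictions
  expect_identical(ensemble_average(pt, 2), pt$preds[[2]])
  # duplicated configuration: average equals either one
  ptd <- prediction_tensor(list(pt$preds[[1]], pt$preds[[1]]), pt$labels)
  avg <- ensemble_average(ptd, c(1, 2))
  expect_equal(avg, pt$preds[[1]], tolerance = 1e-12)
  # random subsets against explicit loops
  set.seed(18)
  for (i in 1:10) {
    ss <- sort(sample(1:3, sample(1:3, 1)))
    got <- ensemble_average(pt, ss)
    for (j in 1:pt$n_folds) {
      expect_equal(got[[j]], oracle_ensemble_average(pt$preds, ss, j),
                   tolerance = 1e-12)
      expect_true(all(abs(rowSums(got[[j]]) - 1) < 1e-9))   # simplex preserved
    }
  }
  expect_error(ensemble_average(pt, integer(0)), "nonempty")
})

test_that("exhaustive search evaluates all subsets and is optimal", {
  pt <- make_tensor(c(0.9, 0, 0, 0), seed = 9, n_img = 60)
  sel <- exhaustive_subset_search(pt)
  expect_equal(nrow(sel$search_log), 2^4 - 1)
  # the strong configuration is always in C*
  expect_true(1 %in% sel$subset)
  # optimality over every evaluated subset, incl. full average and singletons
  expect_true(all(sel$S_star >= sel$search_log$S))
  full_S <- sel$search_log$S[sel$search_log$subset == "1+2+3+4"]
  expect_gte(sel$S_star, full_S)
  for (i in 1:4)
    expect_gte(sel$S_star, sel$search_log$S[sel$search_log$subset == as.character(i)])
  # n = 1 selects the only configuration
  p1 <- make_tensor(0.4, seed = 2)
  s1 <- exhaustive_subset_search(p1)
  expect_equal(s1$subset, 1L)
  # determinism
  expect_identical(exhaustive_subset_search(pt)$subset, sel$subset)
  # cap guard
  p17 <- make_tensor(rep(0.1, 17), seed = 3, n_folds = 2, n_img = 5)
  expect_error(exhaustive_subset_search(p17), "max_configs")
})

test_that("best/last pooling averages aligned tensors", {
  best <- make_tensor(c(0.8, 0.3), seed = 21)
  sel <- exhaustive_subset_search(best)
  # last identical to best: pooled result equals the selection's average
  same <- pool_best_last(sel, best, best)
  expect_equal(same$y_final, sel$y_star, tolerance = 1e-12)
  expect_equal(same$S, sel$S_star)
  # brute-force: mean over 2 * |C*| * m blocks (same held-out labels)
  last <- prediction_tensor(make_tensor(c(0.5, 0.5), seed = 22)$preds,
                            best$labels)
  pooled <- pool_best_last(sel, best, last)
  for (j in 1:best$n_folds) {
    acc <- 0
    for (i in sel$subset) acc <- acc + best$preds[[i]][[j]] + last$preds[[i]][[j]]
    expect_equal(pooled$y_final[[j]], acc / (2 * length(sel$subset)),
                 tolerance = 1e-12)
    expect_true(all(abs(rowSums(pooled$y_final[[j]]) - 1) < 1e-9))
  }
  # misalignment guard
  off <- make_tensor(c(0.5, 0.5), seed = 23, n_img = 41)
  expect_error(pool_best_last(sel, best, off), "misaligned")
})
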